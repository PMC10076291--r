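# Internal helpers shared across modules.
#
# Coordinates are 0-based half-open everywhere inside the package; the GFF3
# writer is the single place they are converted to 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet reverseComplement
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Hamming distance between equal-length strings; any column involving N
# counts as a mismatch (conservative matching).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  n_raw <- charToRaw("N")
  sum(ra != rb | ra == n_raw | rb == n_raw)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

seq_slice <- function(seq, start0, end0) {
  substr(seq, start0 + 1L, end0)
}

seq_replace <- function(seq, start0, repl) {
  n <- nchar(seq)
  m <- nchar(repl)
  stopifnot(start0 >= 0L, start0 + m <= n)
  paste0(substr(seq, 1L, start0), repl, substr(seq, start0 + m + 1L, n))
}

overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Round-half-up (the IEC "banker's" default of round() would turn 0.115
# into 0.11; reported summaries use conventional half-up rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Ungapped identity between two strings over the length of the shorter,
# compared left-aligned. Used for spacer-pair similarity guards.
ungapped_identity <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  if (L == 0L) return(0)
  (L - hamming(substr(a, 1L, L), substr(b, 1L, L))) / L
}

# Derive a stage-local seed from a run seed and a stable label, keeping the
# result a positive 32-bit integer.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Classed error helper so callers/tests can distinguish failure modes.
sl_error <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "spacerlink_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Minimal leveled logger; level controlled via options(spacerlink.log_level=)
# and optionally mirrored to a file via options(spacerlink.log_file=).
.log_levels <- c(debug = 10L, info = 20L, warn = 30L)

sl_log <- function(level, ...) {
  lvl <- .log_levels[[match.arg(level, names(.log_levels))]]
  cur <- .log_levels[[getOption("spacerlink.log_level", "info")]]
  if (lvl < cur) return(invisible(NULL))
  msg <- sprintf("[%s] %s", toupper(level), paste0(..., collapse = ""))
  message(msg)
  file <- getOption("spacerlink.log_file", NULL)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(NULL)
}

# Encode all k-mers of a sequence as integers in base 4 (A=0,C=1,G=2,T=3);
# k-mers containing N (or any other letter) come back NA. Exact for
# k <= 26 (4^26 < 2^53, computed in doubles).
encode_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  code <- integer(256)
  code[] <- NA_integer_
  code[utf8ToInt("A") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L
  code[utf8ToInt("T") + 1L] <- 3L
  d <- code[utf8ToInt(seq) + 1L]
  m <- n - k + 1L
  v <- numeric(m)
  for (i in seq_len(k)) {
    v <- v * 4 + d[i:(i + m - 1L)]
  }
  v
}

# Majority character per column over equal-length strings; returns the
# consensus string and per-column agreement fraction.
column_consensus <- function(strings) {
  L <- nchar(strings[[1]])
  mat <- matrix(unlist(strsplit(strings, "", fixed = TRUE)),
                nrow = length(strings), ncol = L, byrow = TRUE)
  cons <- character(L)
  agree <- numeric(L)
  for (j in seq_len(L)) {
    tab <- table(mat[, j])
    cons[j] <- names(tab)[which.max(tab)]
    agree[j] <- max(tab) / length(strings)
  }
  list(consensus = paste(cons, collapse = ""), agreement = agree)
}
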