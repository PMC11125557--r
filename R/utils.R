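NUC <- c("A", "C", "G", "T")

# package-local cache for subtree-weight matrices and config tables
.ld_cache <- new.env(parent = emptyenv())

#' Convert a Phred quality score to a base-calling error probability
#'
#' @param rho integer (or numeric) Phred score(s).
#' @return error probabilities `10^(-0.1 * rho)`.
#' @examples
#' phred_to_error(30) # 0.001
#' @export
phred_to_error <- function(rho) 10^(-0.1 * rho)

# decode a QUAL string (Phred+33 ASCII) into integer Phred scores
qual_to_phred <- function(qual) {
  lapply(qual, function(q) as.integer(utf8ToInt(q)) - 33L)
}

phred_to_qual <- function(phred) {
  vapply(phred, function(p) intToUtf8(p + 33L), character(1))
}

# all Hamming-distance-1 neighbours of a fragment string
hamming1_neighbours <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(NUC, ch[i])) {
      x <- ch
      x[i] <- b
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

# log-sum-exp
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}
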