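#' @keywords internal
"_PACKAGE"

# Genotype calls are coded internally as integers: 0 = AA, 1 = AB, 2 = BB,
# NA = no call.  The TSV dialect uses the symbol "NC" for no call.
CALL_LEVELS <- c("AA", "AB", "BB")

# Informative CP segregation patterns (JoinMap-style codes).
CP_PATTERNS <- c("hkxhk", "lmxll", "nnxnp")

WHEAT_SUBGENOMES <- c("A", "B", "D")
WHEAT_CHROMOSOMES <- as.vector(outer(1:7, WHEAT_SUBGENOMES, paste0))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All stochastic stages draw their own seed deterministically from one
#' master seed and a stage label, so that adding or reordering stages does
#' not perturb the random numbers used by other stages.
#'
#' @param seed master seed (single integer).
#' @param stage character label of the consuming stage.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "cross") != substream_seed(1, "hits")
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(as.integer(seed))) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# chi-square label of a call-code vector, dropping NA
call_symbol <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- CALL_LEVELS[code[ok] + 1L]
  out
}

code_call <- function(symbol, na_symbols = c("NC", "NoCall", ".", "")) {
  out <- rep(NA_integer_, length(symbol))
  out[symbol == "AA"] <- 0L
  out[symbol == "AB"] <- 1L
  out[symbol == "BB"] <- 2L
  bad <- !(symbol %in% c(CALL_LEVELS, na_symbols)) & !is.na(symbol)
  if (any(bad)) {
    stop2("unknown call symbol(s): ", paste(unique(symbol[bad]), collapse = ", "))
  }
  out
}

# Adjusted Rand index between two labellings (used by tests and the
# acceptance script to compare recovered linkage groups with truth).
#' Adjusted Rand index between two partitions
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return The adjusted Rand index (1 for identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)
  (nij - expected) / (maxi - expected)
}
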