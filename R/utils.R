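#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm quantile rnorm rbinom runif
#' @importFrom utils head tail write.table read.table
#' @importFrom e1071 svm
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed fan-out from one pipeline seed.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stage_ix <- sum(utf8ToInt(as.character(stage))) %% 997L
  as.integer((as.numeric(seed) * 7919 + stage_ix * 104729 + 11) %% 2147483629)
}

round_half_up <- function(x) floor(x + 0.5)

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# character string <-> integer base codes (A=0, C=1, G=2, T=3)
BASES <- c("A", "C", "G", "T")

seq_to_codes <- function(s) {
  r <- charToRaw(s)
  code <- integer(length(r))
  code[r == charToRaw("A")] <- 0L
  code[r == charToRaw("C")] <- 1L
  code[r == charToRaw("G")] <- 2L
  code[r == charToRaw("T")] <- 3L
  code
}

codes_to_seq <- function(code) paste(BASES[code + 1L], collapse = "")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

BASE_RAW <- charToRaw("ACGT")

random_bases_raw <- function(n) BASE_RAW[sample.int(4L, n, replace = TRUE)]

# substitute raw-encoded bases with uniformly chosen different bases
mutate_bases_raw <- function(r) {
  m <- match(r, BASE_RAW)
  m[is.na(m)] <- 1L
  off <- sample.int(3L, length(r), replace = TRUE)
  BASE_RAW[((m - 1L + off) %% 4L) + 1L]
}

# substitute each base with a uniformly chosen *different* base
mutate_bases <- function(bases) {
  off <- sample(1:3, length(bases), replace = TRUE)
  idx <- (match(bases, BASES) - 1L + off) %% 4L
  BASES[idx + 1L]
}
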