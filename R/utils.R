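#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom utils head modifyList
#' @import Rcpp
#' @useDynLib trispectrakan, .registration = TRUE
NULL

# The six diagnosis labels, alphabetical; index i-1 is the class code.
DIAGNOSIS_LEVELS <- c("Bronchiectasis", "Bronchiolitis", "COPD",
                      "Healthy", "Pneumonia", "URTI")

TARGET_RATE_HZ <- 22050L
SEGMENT_SECONDS <- 6

#' Canonical diagnosis labels
#'
#' The closed six-label set recognised throughout the pipeline, in the
#' alphabetical order that defines the integer class encoding
#' (Bronchiectasis = 0, ..., URTI = 5).
#'
#' @return Character vector of length 6.
#' @export
diagnosis_labels <- function() DIAGNOSIS_LEVELS

#' Map a diagnosis label to its integer class code
#'
#' @param label Character vector of diagnosis labels (any case).
#' @return Integer class codes in 0..5.
#' @export
diagnosis_code <- function(label) {
  idx <- match(tolower(label), tolower(DIAGNOSIS_LEVELS))
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    abort(paste0("unknown label ", paste(bad, collapse = ", ")))
  }
  idx - 1L
}

silu <- function(x) x / (1 + exp(-x))

silu_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s * (1 + x * (1 - s))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# deterministic evaluation of `expr` under seed without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# substream seed derivation: stable small-integer hash, kept below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) h <- (h * 31 + (as.numeric(p) %% 1e6)) %% 2147480000
  as.integer(h)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == as.integer(x) && x > 0
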