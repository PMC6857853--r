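# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; diagnostic tables in clinical
#' reporting conventionally round half up. `round_half_up(93.5)` is 94.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(86.5, 87.5), 0)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic per-item seed derivation from a master seed: a simple
# multiplicative counter scheme kept below .Machine$integer.max so the
# result is a valid 32-bit seed. Documented in the configuration reference.
derive_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 10007 + as.double(index)) %% 2147483647)
}

# Validation helper: abort naming the offending field.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "oralcyto_validation_error")
  }
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Otsu threshold on a raw intensity vector (0..255 scale). Implemented on a
# 256-bin histogram; EBImage's otsu() only accepts whole Image objects and we
# need thresholds restricted to in-FOV (or in-mask) pixels.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  h <- as.numeric(tabulate(pmin(pmax(floor(x), 0), 255) + 1L, nbins = 256L))
  w <- cumsum(h)
  n <- w[256L]
  if (n == 0L) return(NA_real_)
  mu <- cumsum(h * (0:255))
  mu_t <- mu[256L]
  w0 <- w[-256L]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_real_)
  mu0 <- mu[-256L] / w0
  mu1 <- (mu_t - mu[-256L]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  # threshold between bin k-1 and k: pixels <= k-1 are "low"
  (k - 1) + 0.5
}

# EBImage interop: package-internal masks/images are [row = y, col = x]
# matrices; EBImage indexes [x, y].
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(im) t(EBImage::imageData(im))

# Connected-component labelling of a logical [H, W] mask.
label_mask <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- from_ebi(EBImage::bwlabel(as_ebi(mask * 1)))
  storage.mode(lab) <- "integer"
  lab
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
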