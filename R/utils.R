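#' Geometric mean
#'
#' Geometric mean of strictly positive values, with optional removal of
#' missing values. Used throughout for normalisation factors, the BestKeeper
#' index and plate-factor fitting.
#'
#' @param x numeric vector, all positive (zeros/negatives are an error).
#' @param na.rm drop missing values first.
#' @return the geometric mean, `NA` if no values remain.
#' @export
gm_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# sample SD with n-1 denominator; NA if fewer than 2 values
sd_n1 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_refstab <- function(msg, class) {
  stop(structure(class = c(class, "refstab_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_refstab(sprintf("'%s' must be a finite numeric scalar", name),
                 "refstab_invalid_argument")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_refstab(sprintf("'%s' = %g is outside its valid range", name, x),
                 "refstab_invalid_argument")
  invisible(x)
}
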