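#' Age transformations for clock regression targets
#'
#' An `age_transform` describes the invertible map applied to chronological
#' age before it is used as the dependent variable of a penalized regression,
#' and inverted to report clock output in years.
#'
#' Three kinds are supported:
#' \describe{
#'   \item{identity}{age in years, unchanged. Used for single-species
#'     pan-tissue and tissue-specific clocks.}
#'   \item{relative}{age divided by the species' maximum recorded lifespan,
#'     mapping every species onto a common `[0, 1]` scale. A macaque at 40 of
#'     a 42-year maximum lifespan is then *older* than a human at 40 of
#'     122.5 years, which a raw-age clock cannot express.}
#'   \item{loglinear}{a piecewise transform of chronological age, logarithmic
#'     before the species' age of sexual maturity and linear after it:
#'     `log((age + offset) / (m + offset))` for `age <= m`, and
#'     `(age - m) / (m + offset)` for `age > m`, with maturity age `m` and a
#'     positive `offset` (default 1 year). The two branches agree in value (0)
#'     and first derivative (`1 / (m + offset)`) at the knot, so the transform
#'     is continuous, differentiable and strictly increasing, hence exactly
#'     invertible. This is the standard construction for dual-species
#'     chronological-age clocks, compressing the fast juvenile methylation
#'     drift while keeping adult ages on a linear scale.}
#' }
#'
#' Species constants (`max_lifespan`, `maturity_age`) are *not* stored in the
#' transform: they are per-species columns of the sample sheet, so one fitted
#' clock applies to any species for which the constants are known.
#'
#' @param kind One of `"identity"`, `"relative"`, `"loglinear"`.
#' @param offset Positive offset in years for the log-linear knee; ignored by
#'   the other kinds.
#' @return An object of class `age_transform`.
#' @examples
#' tr <- age_transform("relative")
#' transform_age(tr, age = 21, max_lifespan = 42)
#' @export
age_transform <- function(kind = c("identity", "relative", "loglinear"),
                          offset = 1) {
  kind <- match.arg(kind)
  if (kind == "loglinear" && (!is.numeric(offset) || offset <= 0)) {
    stop("`offset` must be a positive number of years")
  }
  structure(list(kind = kind, offset = offset), class = "age_transform")
}

#' @exportS3Method base::print
print.age_transform <- function(x, ...) {
  cat("<age_transform>", x$kind,
      if (x$kind == "loglinear") sprintf("(offset = %g y)", x$offset), "\n")
  invisible(x)
}

#' Relative age
#'
#' Chronological age divided by the species' maximum recorded lifespan
#' (42 y for rhesus macaque, 122.5 y for human per the anAge database),
#' aligning species of very different lifespans on a common `[0, 1]` scale.
#'
#' @param age Age(s) in years, non-negative.
#' @param max_lifespan Maximum lifespan(s) in years, positive; recycled.
#' @return `age / max_lifespan`. Values above 1 are permitted (with a
#'   warning) since predicted ages can exceed the recorded maximum.
#' @examples
#' relative_age(42, 42)      # 1: macaque at maximum lifespan
#' relative_age(61.25, 122.5) # 0.5: human at mid-lifespan
#' @export
relative_age <- function(age, max_lifespan) {
  if (any(!is.finite(max_lifespan)) || any(max_lifespan <= 0)) {
    stop("`max_lifespan` must be positive and finite")
  }
  if (any(age < 0)) stop("`age` must be non-negative")
  if (any(age > max_lifespan)) {
    warning("age exceeds max_lifespan; relative age > 1 returned")
  }
  age / max_lifespan
}

#' Log-linear age transform and its inverse
#'
#' Logarithmic below the maturity knot, linear above it; see
#' [age_transform()] for the closed form and its properties.
#'
#' @param age Age(s) in years, non-negative.
#' @param maturity_age Age of sexual maturity in years, positive.
#' @param offset Positive offset in years; controls curvature near birth.
#' @return Transformed value(s); 0 at `age == maturity_age`.
#' @export
loglinear_age <- function(age, maturity_age, offset = 1) {
  if (any(offset <= 0)) stop("`offset` must be positive")
  if (any(maturity_age <= 0)) stop("`maturity_age` must be positive")
  if (any(age < 0)) stop("`age` must be non-negative")
  k <- maturity_age + offset
  ifelse(age <= maturity_age, log((age + offset) / k), (age - maturity_age) / k)
}

#' @rdname loglinear_age
#' @param value Transformed value(s) to map back to years.
#' @export
loglinear_inverse <- function(value, maturity_age, offset = 1) {
  if (any(offset <= 0)) stop("`offset` must be positive")
  k <- maturity_age + offset
  ifelse(value <= 0, k * exp(value) - offset, maturity_age + value * k)
}

#' Apply or invert an age transform
#'
#' Vectorized over samples; `max_lifespan` / `maturity_age` may be vectors
#' (one per sample) so a single call handles mixed-species data.
#'
#' @param transform An [age_transform()].
#' @param age Ages in years (for the forward direction).
#' @param value Transformed values (for the inverse direction).
#' @param max_lifespan Per-sample maximum lifespan in years (`relative` only).
#' @param maturity_age Per-sample maturity age in years (`loglinear` only).
#' @return Transformed values, or ages in years for the inverse.
#' @export
transform_age <- function(transform, age, max_lifespan = NULL,
                          maturity_age = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
    identity = age,
    relative = {
      if (is.null(max_lifespan)) stop("relative transform needs `max_lifespan`")
      relative_age(age, max_lifespan)
    },
    loglinear = {
      if (is.null(maturity_age)) stop("loglinear transform needs `maturity_age`")
      loglinear_age(age, maturity_age, transform$offset)
    }
  )
}

#' @rdname transform_age
#' @export
inverse_transform_age <- function(transform, value, max_lifespan = NULL,
                                  maturity_age = NULL) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
    identity = value,
    relative = {
      if (is.null(max_lifespan)) stop("relative transform needs `max_lifespan`")
      value * max_lifespan
    },
    loglinear = {
      if (is.null(maturity_age)) stop("loglinear transform needs `maturity_age`")
      loglinear_inverse(value, maturity_age, transform$offset)
    }
  )
}

# transform ages taken from a sample sheet, using its per-species constants
transform_sheet_ages <- function(transform, sheet) {
  transform_age(transform, sheet$age,
                max_lifespan = sheet$max_lifespan,
                maturity_age = sheet$maturity_age)
}
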