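#' Location (mean-structure) model specification
#'
#' Declares the fixed occasion-varying regressors, fixed subject-level
#' regressors, and which occasion-varying terms carry random subject
#' effects.  The term \code{"1"} denotes the intercept and is present by
#' default; random terms must be a subset of the occasion-varying terms.
#'
#' @param x_terms occasion-varying regressor names (always includes "1").
#' @param w_terms subject-level regressor names.
#' @param random subset of \code{x_terms} with random effects (default the
#'   intercept only).
#' @return A \code{location_spec} object.
#' @export
location_spec <- function(x_terms = character(), w_terms = character(),
                          random = "1") {
  x_terms <- union("1", x_terms)
  if (!all(random %in% x_terms))
    stop("random terms must be a subset of x_terms")
  if (!length(random)) stop("at least one random location term is required")
  structure(list(x_terms = x_terms, w_terms = w_terms, random = random),
            class = "location_spec")
}

#' Between-subject variance model specification
#'
#' Log-linear model for the variance of each random location effect:
#' the variance is \code{exp(alpha0 + alpha' w)} with an intercept always
#' present.  With several random effects their correlations are additional
#' free parameters, held covariate-free.
#'
#' @param terms subject-level regressor names entering the log-variance.
#' @return A \code{between_spec} object.
#' @export
between_spec <- function(terms = character()) {
  structure(list(terms = terms), class = "between_spec")
}

#' Within-subject (residual) variance model specification
#'
#' Log-linear model for the occasion-level residual variance:
#' \code{exp(tau0 + tau_x' x + tau_w' w + a_i)}, where \code{a_i} is a
#' normally distributed random scale effect with variance \code{phi_a^2},
#' included when \code{random_scale = TRUE}.
#'
#' @param x_terms occasion-varying regressor names.
#' @param w_terms subject-level regressor names.
#' @param random_scale include the random scale effect \code{a_i}?
#' @return A \code{within_spec} object.
#' @export
within_spec <- function(x_terms = character(), w_terms = character(),
                        random_scale = TRUE) {
  structure(list(x_terms = x_terms, w_terms = w_terms,
                 random_scale = isTRUE(random_scale)),
            class = "within_spec")
}

#' Full model specification
#'
#' Bundles the location, between-variance, within-variance and (optionally)
#' measurement submodels.  Without a measurement model the outcome column
#' is modelled directly (manifest mode); with one, the item responses load
#' on an occasion-specific latent variable that follows the location scale
#' model (latent mode).
#'
#' @param location a [location_spec].
#' @param between a [between_spec].
#' @param within a [within_spec].
#' @param measurement a [measurement_spec], or \code{NULL} for manifest mode.
#' @return A \code{melsm_spec} object.
#' @export
melsm_spec <- function(location = location_spec(),
                       between = between_spec(),
                       within = within_spec(),
                       measurement = NULL) {
  stopifnot(inherits(location, "location_spec"),
            inherits(between, "between_spec"),
            inherits(within, "within_spec"))
  if (!is.null(measurement) && !inherits(measurement, "measurement_spec"))
    stop("`measurement` must be a measurement_spec or NULL")
  structure(list(location = location, between = between, within = within,
                 measurement = measurement),
            class = "melsm_spec")
}

is_latent <- function(spec) !is.null(spec$measurement)

## resolve term names ("1" = intercept) to a design matrix over given rows
terms_matrix <- function(df, terms, n) {
  if (!length(terms)) return(matrix(numeric(0), n, 0))
  cols <- lapply(terms, function(tm) {
    if (identical(tm, "1")) rep(1, n)
    else {
      if (!tm %in% names(df))
        stop("unknown term `", tm, "`; available columns: ",
             paste(names(df), collapse = ", "))
      df[[tm]]
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- ifelse(terms == "1", "(Intercept)", terms)
  m
}

#' Assemble per-subject design matrices
#'
#' For every subject builds the stacked fixed-effects design
#' \code{Gamma_i} (occasion-varying terms followed by subject-level terms),
#' the random-effect design \code{Z_i}, the within-variance design
#' \code{V_i} (intercept, occasion-varying, subject-level terms) and the
#' between-variance design row \code{B_i} (intercept plus subject-level
#' terms), together with the response for that subject.
#'
#' @param data a [diary_data] object.
#' @param spec a [melsm_spec] (or the three submodel specs via \code{...}).
#' @return A list with one element per subject, each containing
#'   \code{subject}, \code{occasions}, \code{n}, \code{Gamma}, \code{Z},
#'   \code{V}, \code{B}, and \code{y} (vector in manifest mode; an
#'   occasions x items matrix with \code{NA} for missing cells in latent
#'   mode).
#' @export
build_designs <- function(data, spec) {
  stopifnot(inherits(data, "diary_data"), inherits(spec, "melsm_spec"))
  sid <- data[[dd_attr(data, "subject")]]
  subjects <- unique(sid)
  loc <- spec$location; bv <- spec$between; wv <- spec$within
  items <- dd_attr(data, "items")
  outcome <- dd_attr(data, "outcome")

  lapply(subjects, function(s) {
    df <- as.data.frame(data)[sid == s, , drop = FALSE]
    n <- nrow(df)
    X <- terms_matrix(df, loc$x_terms, n)
    W <- terms_matrix(df, loc$w_terms, n)
    Gamma <- cbind(X, W)
    Z <- X[, match(loc$random, loc$x_terms), drop = FALSE]
    V <- cbind(terms_matrix(df, "1", n),
               terms_matrix(df, wv$x_terms, n),
               terms_matrix(df, wv$w_terms, n))
    B <- c(terms_matrix(df, "1", 1L)[1, ],
           if (length(bv$terms)) sapply(bv$terms, function(tm) df[[tm]][1]))
    names(B) <- c("(Intercept)", bv$terms)
    y <- if (is.null(items)) df[[outcome]] else {
      m <- as.matrix(df[, items, drop = FALSE])
      dimnames(m) <- list(NULL, items)
      m
    }
    list(subject = s, occasions = df[[dd_attr(data, "occasion")]], n = n,
         Gamma = Gamma, Z = Z, V = V, B = B, y = y)
  })
}
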