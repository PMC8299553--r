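#' Candidate function terms and libraries
#'
#' A Langevin model is parameterized as a linear combination of candidate
#' functions: the drift is `f(x) = sum_j xi_f[j] * theta_j(x)` and the noise
#' amplitude is `sigma(x) = sum_j xi_s[j] * phi_j(x)`. `function_term()`
#' creates one candidate; `function_library()` collects an ordered set of
#' them. Only polynomial terms are supported, which keeps every term
#' representable by its degree (and makes simulation of fitted models cheap).
#'
#' @param degree Non-negative integer, the monomial degree.
#' @param kind Either `"drift"` or `"diffusion"`; which part of the model the
#'   term is a candidate for.
#' @param name Optional label; defaults to `"1"` for degree 0 and `"x^d"`
#'   otherwise.
#' @return `function_term()` returns an object of class `"function_term"`
#'   with fields `name`, `degree`, `kind` and `evaluator` (a pure function of
#'   a numeric vector).
#' @examples
#' cube <- function_term(3, "drift")
#' cube$evaluator(2) # 8
#' @export
function_term <- function(degree, kind = c("drift", "diffusion"), name = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(degree) || length(degree) != 1L || degree < 0 ||
      degree != round(degree)) {
    lr_error("'degree' must be a single non-negative integer", "invalid_argument")
  }
  degree <- as.integer(degree)
  if (is.null(name)) {
    name <- if (degree == 0L) "1" else if (degree == 1L) "x" else
      paste0("x^", degree)
  }
  ev <- local({
    d <- degree
    function(x) x^d
  })
  structure(
    list(name = name, degree = degree, kind = kind, evaluator = ev),
    class = "function_term"
  )
}

#' @rdname function_term
#' @param terms List of `function_term` objects (all of the same `kind`,
#'   unique names).
#' @param parity `"all"`, `"odd"` or `"even"`: a declared symmetry of the
#'   library. Every term must have a degree of matching parity.
#' @export
function_library <- function(terms, parity = c("all", "odd", "even")) {
  parity <- match.arg(parity)
  if (length(terms) == 0L) {
    lr_error("a function library must contain at least one term", "invalid_argument")
  }
  if (!all(vapply(terms, inherits, logical(1), "function_term"))) {
    lr_error("all elements of 'terms' must be function_term objects", "invalid_argument")
  }
  nms <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    lr_error("term names must be unique within a library", "invalid_argument")
  }
  degs <- vapply(terms, `[[`, integer(1), "degree")
  if (parity == "odd" && any(degs %% 2L == 0L)) {
    lr_error("parity 'odd' library contains an even-degree term", "invalid_argument")
  }
  if (parity == "even" && any(degs %% 2L == 1L)) {
    lr_error("parity 'even' library contains an odd-degree term", "invalid_argument")
  }
  structure(
    list(terms = terms, parity = parity),
    class = "function_library"
  )
}

#' Build a polynomial candidate library
#'
#' Returns the monomials `x^0, ..., x^max_degree`, filtered by parity and
#' ordered by degree. A typical symmetry-respecting choice for a pitchfork
#' system is an odd drift library (`x, x^3, x^5`) and an even diffusion
#' library (`1, x^2`).
#'
#' @param max_degree Highest degree to include (>= 0).
#' @param parity `"all"`, `"odd"` or `"even"`.
#' @param kind `"drift"` or `"diffusion"`.
#' @return A `function_library`.
#' @examples
#' names(polynomial_library(5, "odd", "drift")) # "x" "x^3" "x^5"
#' @export
polynomial_library <- function(max_degree, parity = c("all", "odd", "even"),
                               kind = c("drift", "diffusion")) {
  parity <- match.arg(parity)
  kind <- match.arg(kind)
  if (!is.numeric(max_degree) || length(max_degree) != 1L || max_degree < 0) {
    lr_error("'max_degree' must be a non-negative integer", "invalid_argument")
  }
  degs <- 0:as.integer(max_degree)
  degs <- switch(parity,
    all  = degs,
    odd  = degs[degs %% 2L == 1L],
    even = degs[degs %% 2L == 0L]
  )
  if (length(degs) == 0L) {
    lr_error("no terms survive the parity filter", "invalid_argument")
  }
  function_library(lapply(degs, function_term, kind = kind), parity = parity)
}

#' @export
length.function_library <- function(x) length(x$terms)

#' @export
names.function_library <- function(x) {
  vapply(x$terms, `[[`, character(1), "name")
}

#' @export
print.function_library <- function(x, ...) {
  cat(sprintf("<function_library> %d term(s), parity = %s: %s\n",
              length(x), x$parity, paste(names(x), collapse = ", ")))
  invisible(x)
}

# Degrees of the terms of a library (internal helper).
library_degrees <- function(lib) {
  vapply(lib$terms, `[[`, integer(1), "degree")
}

# Evaluate the library design matrix Theta(x): one column per term.
library_matrix <- function(lib, x) {
  m <- vapply(lib$terms, function(tm) tm$evaluator(x), numeric(length(x)))
  matrix(m, nrow = length(x), ncol = length(lib$terms))
}
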