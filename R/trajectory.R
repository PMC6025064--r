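## Containers for time-resolved relative-importance results.

#' Importance trajectory
#'
#' A time grid x attribute matrix of relative-importance values (Shapley
#' values from the Choquet path, or LMG shares). Rows of a Shapley
#' trajectory, and of a normalized LMG trajectory, sum to 1.
#'
#' @param times Numeric grid in seconds.
#' @param values Matrix, length(times) x n attributes; column names are the
#'   attribute labels.
#' @param method "shapley" or "lmg".
#' @param diagnostics Optional per-time list of fit summaries.
#' @return An `importance_trajectory`.
#' @export
importance_trajectory <- function(times, values, method = c("shapley", "lmg"),
                                  diagnostics = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != length(times))
    stop("values must have one row per time point")
  if (is.null(colnames(values))) stop("values must have attribute column names")
  structure(list(times = as.numeric(times), attributes = colnames(values),
                 values = values, method = method, diagnostics = diagnostics),
            class = "importance_trajectory")
}

#' @export
print.importance_trajectory <- function(x, ...) {
  cat(sprintf("Importance trajectory (%s): %d time points x %d attributes [%g..%g s]\n",
              x$method, length(x$times), length(x$attributes),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Canonical label for an attribute pair
#'
#' Pairs are labeled `"<Ai>v<Aj>"` with i < j in the trajectory's attribute
#' order, and enumerated in combination order — the conventional column
#' scheme for printed interaction tables (e.g., "HvC", "HvM", ..., "MvA"
#' for attributes H, C, M, A).
#'
#' @param attributes Attribute labels in order.
#' @return Character vector of n(n-1)/2 pair labels.
#' @export
pair_labels <- function(attributes) {
  n <- length(attributes)
  out <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out <- c(out, paste0(attributes[i], "v", attributes[j]))
  out
}

#' Interaction trajectory
#'
#' A time grid x attribute-pair matrix of pairwise interaction indices, each
#' in \[-1, 1\] (positive = complementary, negative = substitutive).
#'
#' @param times Numeric grid in seconds.
#' @param values Matrix, length(times) x n(n-1)/2 pairs, columns in the
#'   canonical [pair_labels()] order.
#' @param attributes The underlying attribute labels.
#' @return An `interaction_trajectory`.
#' @export
interaction_trajectory <- function(times, values, attributes) {
  values <- as.matrix(values)
  labs <- pair_labels(attributes)
  if (ncol(values) != length(labs))
    stop("expected one column per attribute pair")
  colnames(values) <- labs
  if (nrow(values) != length(times))
    stop("values must have one row per time point")
  structure(list(times = as.numeric(times), attributes = attributes,
                 pairs = labs, values = values),
            class = "interaction_trajectory")
}

#' @export
print.interaction_trajectory <- function(x, ...) {
  cat(sprintf("Interaction trajectory: %d time points x %d pairs [%g..%g s]\n",
              length(x$times), length(x$pairs), min(x$times), max(x$times)))
  invisible(x)
}
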