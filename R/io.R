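## Delimited-text readers/writers and packaged reference tables. All tabular
## I/O is comma-separated UTF-8 with "." decimal and a mandatory header;
## numbers are parsed in the C locale by read.csv/write.csv.

mati_scales <- list(
  line       = list(type = "line",       range = c(0, 150)),
  proportion = list(type = "proportion", range = c(0, 1)),
  jar        = list(type = "jar",        range = c(-1, 1)),
  liking     = list(type = "liking",     range = c(0, 100))
)

#' Construct a validated MATI dataset
#'
#' Long-format time-intensity records: one row per (observer, product,
#' attribute, time) with a single rating value. The observer column may be
#' empty (e.g., panel-mean data). Declared scales: `"line"` (0-150
#' line-scale points), `"proportion"` (0-1, CATA item proportions), `"jar"`
#' (exact membership in \{-1, 0, +1\}), `"liking"` (0-100).
#'
#' @param records Data frame with columns `observer`, `product`, `attribute`,
#'   `time_s`, `value` (missing `observer` column is filled with "").
#' @param scale One of "line", "proportion", "jar", "liking", or a list with
#'   `type` and `range`.
#' @return A `mati_dataset` (a data frame with scale metadata attached).
#' @export
mati_dataset <- function(records, scale = "line") {
  if (is.character(scale)) {
    if (!scale %in% names(mati_scales))
      stop("unknown scale '", scale, "'")
    scale <- mati_scales[[scale]]
  }
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"observer" %in% names(df)) df$observer <- ""
  required <- c("observer", "product", "attribute", "time_s", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$observer <- as.character(df$observer)
  df$product <- as.character(df$product)
  df$attribute <- as.character(df$attribute)
  df$time_s <- as.numeric(df$time_s)
  df$value <- as.numeric(df$value)

  na_val <- is.na(df$value)
  if (any(na_val)) {
    warning(sprintf("dropped %d record(s) with missing value (rows: %s)",
                    sum(na_val),
                    paste(utils::head(which(na_val), 5), collapse = ", ")))
    df <- df[!na_val, , drop = FALSE]
  }
  if (any(is.na(df$time_s)) || any(df$time_s < 0))
    stop("time_s must be nonnegative and non-missing")

  key <- paste(df$observer, df$product, df$attribute, df$time_s, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop(sprintf("duplicate (observer, product, attribute, time) key at row %d",
                 which(dup)[1]))

  if (identical(scale$type, "jar")) {
    bad <- !(df$value %in% c(-1, 0, 1))
  } else {
    bad <- df$value < scale$range[1] - 1e-9 | df$value > scale$range[2] + 1e-9
  }
  if (any(bad))
    stop(sprintf("value out of declared %s range at row %d (value = %g)",
                 scale$type, which(bad)[1], df$value[which(bad)[1]]))

  rownames(df) <- NULL
  structure(df, scale = scale, class = c("mati_dataset", "data.frame"))
}

#' Read a long-format MATI table from CSV
#'
#' @param path File path; header mandatory; columns `observer` (optional),
#'   `product`, `attribute`, `time_s`, `value`.
#' @param scale Declared scale, see [mati_dataset()].
#' @return A validated `mati_dataset`; row order preserved.
#' @export
read_mati_csv <- function(path, scale = "line") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("product", "attribute", "time_s", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  mati_dataset(df, scale = scale)
}

#' Write a MATI dataset to CSV
#'
#' @param dataset A `mati_dataset`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mati_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "mati_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an importance or interaction trajectory to CSV
#'
#' One row per grid time; header is `second` followed by the attribute (or
#' canonical pair) labels. Values are written with 15 significant digits so
#' a read-back matches to at least 12 significant digits.
#'
#' @param trajectory An `importance_trajectory` or `interaction_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, c("importance_trajectory",
                                   "interaction_trajectory")))
  labs <- colnames(trajectory$values)
  lines <- c(paste(c("second", labs), collapse = ","),
             vapply(seq_along(trajectory$times), function(i)
               paste(c(format(trajectory$times[i], digits = 15),
                       format(trajectory$values[i, ], digits = 15,
                              scientific = FALSE, trim = TRUE)),
                     collapse = ","), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' @param path File path.
#' @param method "shapley" or "lmg" (importance), or "interaction"; for
#'   "interaction" the attribute labels are recovered from the pair columns.
#' @return An `importance_trajectory` or `interaction_trajectory`.
#' @export
read_trajectory_csv <- function(path, method = "shapley") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "second") stop("first column must be 'second'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (method == "interaction") {
    attrs <- unique(unlist(strsplit(colnames(vals), "v", fixed = TRUE)))
    interaction_trajectory(df$second, vals, attrs)
  } else {
    importance_trajectory(df$second, vals, method = method)
  }
}

#' Packaged reference importance tables (fruit-chews study)
#'
#' Four published time-resolved relative-importance tables for a fruit-chews
#' MATI study, transcribed and bundled as plain text: Shapley values of 4
#' texture attributes on the 3-90 s grid (step 3), the matching pairwise
#' interaction indices, Shapley values of 5 first-bite CATA items on 1-25 s,
#' and LMG shares of 3 just-about-right flavor attributes on 14-90 s
#' (step 4). They are consistency fixtures — published outputs whose raw
#' inputs are not available — not fitting targets.
#'
#' @return A list with elements `texture_shapley`, `texture_interactions`
#'   (an `interaction_trajectory`), `cata_shapley`, `jar_lmg`.
#' @export
load_reference_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "tdol", mustWork = TRUE)
  rd <- function(f) utils::read.delim(ext(f), check.names = FALSE)
  t1 <- rd("fruitchew_texture_shapley.tsv")
  t2 <- rd("fruitchew_texture_interactions.tsv")
  t3 <- rd("fruitchew_cata_shapley.tsv")
  t4 <- rd("fruitchew_jar_lmg.tsv")
  list(
    texture_shapley = importance_trajectory(
      t1$second, as.matrix(t1[-1]), method = "shapley"),
    texture_interactions = interaction_trajectory(
      t2$second, as.matrix(t2[-1]),
      attributes = c("H", "C", "M", "A")),
    cata_shapley = importance_trajectory(
      t3$second, as.matrix(t3[-1]), method = "shapley"),
    jar_lmg = importance_trajectory(
      t4$second, as.matrix(t4[-1]), method = "lmg")
  )
}

#' Serialize a capacity or Möbius representation to JSON text
#'
#' Subset entries are keyed by their member attribute names joined with "+"
#' ("{}" for the empty set); numbers are written at full precision so the
#' round trip through [capacity_from_json()] is bit-exact.
#'
#' @param x A `capacity` or `mobius_capacity`.
#' @return A JSON string.
#' @export
capacity_to_json <- function(x) {
  n <- length(x$attributes)
  labs <- vapply(0:(2^n - 1L), subset_label, "", attributes = x$attributes)
  if (inherits(x, "capacity")) {
    jsonlite::toJSON(list(representation = "capacity",
                          attributes = x$attributes,
                          values = as.list(stats::setNames(x$values, labs))),
                     auto_unbox = TRUE, digits = I(17))
  } else if (inherits(x, "mobius_capacity")) {
    jsonlite::toJSON(list(representation = "mobius",
                          attributes = x$attributes,
                          k_additive = x$k_additive,
                          coefficients = as.list(stats::setNames(x$coefficients, labs))),
                     auto_unbox = TRUE, digits = I(17))
  } else stop("not a capacity or mobius_capacity")
}

#' Restore a capacity from JSON text
#'
#' @param txt JSON produced by [capacity_to_json()].
#' @return A `capacity` or `mobius_capacity`, matching what was serialized.
#' @export
capacity_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  attrs <- o$attributes
  n <- length(attrs)
  labs <- vapply(0:(2^n - 1L), subset_label, "", attributes = attrs)
  if (identical(o$representation, "capacity")) {
    capacity(as.numeric(o$values[labs]), attrs)
  } else {
    mobius_capacity(as.numeric(o$coefficients[labs]), attrs,
                    k_additive = o$k_additive)
  }
}
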