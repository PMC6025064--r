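## Synthetic MATI fixtures with known ground truth. The generator emulates
## the study conditions the package targets: a small product set profiled by
## a trained panel on 0-150 line scales with time-intensity curves peaking
## near 10 s then decaying, consumer liking on a 0-100 line scale, 3-level
## just-about-right responses, and CATA item proportions over the first bite.
## Every function routes all randomness through one seeded stream, so fixed
## seeds give bitwise-identical tables.

#' Simulation configuration
#'
#' @param n_products,n_attributes,n_panelists,n_consumers Positive counts.
#'   Defaults mirror a small guidance study: 3 products, 4 texture
#'   attributes, 9 trained panelists, 40 consumers.
#' @param t_min,t_max,step Sampling grid in seconds (default 3-90 step 3).
#' @param peak_time Seconds at which time-intensity curves peak (default 10).
#' @param noise_sd Rating noise standard deviation in scale units
#'   (default 8 on the 0-150 line scale).
#' @param generator One of "capacity", "linear", "jar".
#' @param attributes Optional attribute labels (default Attr1..AttrK).
#' @param level_probs For the "jar" generator: length-3 probabilities of
#'   levels (-1, 0, +1), recycled over attributes/times, or a matrix with one
#'   row per attribute.
#' @param penalties For the "jar" generator: named per-attribute liking
#'   penalty (0-100 scale units) applied when the response is not
#'   "just about right".
#' @param baseline Baseline liking for the "jar" generator (0-100).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_products = 3, n_attributes = 4, n_panelists = 9,
                       n_consumers = 40, t_min = 3, t_max = 90, step = 3,
                       peak_time = 10, noise_sd = 8,
                       generator = c("capacity", "linear", "jar"),
                       attributes = NULL,
                       level_probs = c(0.35, 0.50, 0.15),
                       penalties = NULL, baseline = 75, seed = 1) {
  generator <- match.arg(generator)
  stopifnot(n_products >= 1, n_attributes >= 1, n_panelists >= 1,
            n_consumers >= 1, noise_sd >= 0, t_max > t_min, step > 0,
            peak_time > 0)
  if (is.null(attributes))
    attributes <- paste0("Attr", seq_len(n_attributes))
  stopifnot(length(attributes) == n_attributes)
  if (is.matrix(level_probs)) {
    stopifnot(nrow(level_probs) == n_attributes, ncol(level_probs) == 3)
  } else {
    stopifnot(length(level_probs) == 3)
    level_probs <- matrix(level_probs, n_attributes, 3, byrow = TRUE)
  }
  if (any(abs(rowSums(level_probs) - 1) > 1e-9))
    stop("level probabilities must sum to 1 per attribute")
  if (is.null(penalties))
    penalties <- stats::setNames(rep(10, n_attributes), attributes)
  structure(list(n_products = n_products, n_attributes = n_attributes,
                 n_panelists = n_panelists, n_consumers = n_consumers,
                 t_min = t_min, t_max = t_max, step = step,
                 peak_time = peak_time, noise_sd = noise_sd,
                 generator = generator, attributes = attributes,
                 level_probs = level_probs, penalties = penalties,
                 baseline = baseline, seed = seed),
            class = "sim_config")
}

## gamma-density-shaped rise/decay normalized to peak 1 at tp:
## s(t) = (t/tp)^a exp(a (1 - t/tp)); larger a = steeper decay
ti_shape <- function(t, tp, a) (t / tp)^a * exp(a * (1 - t / tp))

#' Generate panel multi-attribute time-intensity curves
#'
#' Per product x attribute a gamma-shaped rise-decay base curve on the 0-150
#' line scale peaking at `peak_time`; per panelist, Gaussian rating noise
#' truncated to the legal range. Product profiles cross: each product draws
#' its own amplitude per attribute (prototypes typically trade one attribute
#' off against another), with mild product-specific variation in decay.
#'
#' @param cfg A [sim_config()].
#' @return A `mati_dataset` (scale "line") with one record per panelist x
#'   product x attribute x grid time. The noiseless panel-mean base curves
#'   are attached as `attr(, "truth")` (long data frame, observer = "").
#' @export
gen_mati_curves <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- local_rng(cfg$seed)
  times <- seq(cfg$t_min, cfg$t_max, by = cfg$step)
  prods <- paste0("P", seq_len(cfg$n_products))
  amp_attr <- rng$runif(cfg$n_attributes, 80, 140)
  decay_attr <- rng$runif(cfg$n_attributes, 1.5, 3)
  prod_mix <- matrix(rng$runif(cfg$n_products * cfg$n_attributes, 0.55, 1),
                     cfg$n_products, cfg$n_attributes)
  dec_jit <- matrix(rng$runif(cfg$n_products * cfg$n_attributes, 0.9, 1.1),
                    cfg$n_products, cfg$n_attributes)

  truth <- list(); rows <- list()
  for (p in seq_len(cfg$n_products)) for (a in seq_len(cfg$n_attributes)) {
    amp <- min(amp_attr[a] * prod_mix[p, a], 150)
    base <- amp * ti_shape(times, cfg$peak_time, decay_attr[a] * dec_jit[p, a])
    truth[[length(truth) + 1L]] <- data.frame(
      observer = "", product = prods[p], attribute = cfg$attributes[a],
      time_s = times, value = base, stringsAsFactors = FALSE)
    for (o in seq_len(cfg$n_panelists)) {
      val <- base + rng$rnorm(length(times), 0, cfg$noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        observer = paste0("panelist", o), product = prods[p],
        attribute = cfg$attributes[a], time_s = times,
        value = pmin(pmax(val, 0), 150), stringsAsFactors = FALSE)
    }
  }
  out <- mati_dataset(do.call(rbind, rows), scale = "line")
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Aggregate a MATI dataset to observer means
#'
#' Mean value across observers for each (product, attribute, time).
#'
#' @param dataset A `mati_dataset`.
#' @return A `mati_dataset` with observer = "" and the same scale.
#' @export
mati_means <- function(dataset) {
  stopifnot(inherits(dataset, "mati_dataset"))
  agg <- stats::aggregate(value ~ product + attribute + time_s,
                          data = as.data.frame(dataset), FUN = mean)
  agg$observer <- ""
  mati_dataset(agg, scale = attr(dataset, "scale"))
}

#' Generate consumer-mean liking from a known capacity
#'
#' Ground-truth liking for Choquet-path recovery tests: at each grid time the
#' panel-mean attribute values are min-max scaled across products (the same
#' commensurability convention the fitting pipeline uses), aggregated by the
#' Choquet integral of the supplied capacity, mapped to the 0-100 liking
#' scale, and perturbed with truncated Gaussian noise. The generating Shapley
#' values and interaction indices are attached as `attr(, "truth")`.
#'
#' @param panel_means A `mati_dataset` of panel means (observer = ""), e.g.,
#'   from [mati_means()] or the truth slot of [gen_mati_curves()].
#' @param capacity A `mobius_capacity` whose attributes match the panel's.
#' @param noise_sd Liking noise sd on the 0-100 scale.
#' @param seed Integer seed.
#' @param attribute_label Label used for the liking series.
#' @return A `mati_dataset` (scale "liking") with one record per product x
#'   time, attribute = `attribute_label`.
#' @export
gen_liking_from_capacity <- function(panel_means, capacity, noise_sd = 0,
                                     seed = 1, attribute_label = "OverallLiking") {
  stopifnot(inherits(capacity, "mobius_capacity"))
  df <- as.data.frame(panel_means)
  attrs <- capacity$attributes
  if (!setequal(unique(df$attribute), attrs))
    stop("capacity attributes must match the panel attributes")
  rng <- local_rng(seed)
  times <- sort(unique(df$time_s))
  prods <- sort(unique(df$product))
  rows <- list()
  for (t in times) {
    X <- sapply(attrs, function(a)
      sapply(prods, function(p)
        df$value[df$product == p & df$attribute == a & df$time_s == t][1]))
    X <- matrix(X, length(prods), length(attrs),
                dimnames = list(prods, attrs))
    S <- scale_minmax(X)$scaled
    l01 <- apply(S, 1, function(r) choquet(capacity, r))
    lik <- 100 * l01 + rng$rnorm(length(prods), 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      observer = "", product = prods, attribute = attribute_label,
      time_s = t, value = pmin(pmax(lik, 0), 100), stringsAsFactors = FALSE)
  }
  out <- mati_dataset(do.call(rbind, rows), scale = "liking")
  attr(out, "truth") <- list(mobius = capacity,
                             shapley = shapley(capacity),
                             interactions = interaction_matrix(capacity))
  out
}

#' Generate per-time consumer just-about-right tables with liking
#'
#' At each grid time every consumer's JAR level per attribute is drawn from
#' the configured level probabilities; liking on the 0-100 scale is the
#' baseline minus the attribute's penalty for each non-just-right response,
#' plus truncated Gaussian noise. The attribute with the largest penalty is
#' the generating dominant driver (stored in `attr(, "truth")`).
#'
#' @param cfg A [sim_config()] with `generator = "jar"`; the JAR grid
#'   defaults to 14-90 s step 4 unless the config grid says otherwise.
#' @return A list with `jar` (a `mati_dataset`, scale "jar", observer =
#'   consumer id) and `liking` (a `mati_dataset`, scale "liking", one record
#'   per consumer x time).
#' @export
gen_jar_consumer_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$generator != "jar") stop("cfg$generator must be 'jar'")
  rng <- local_rng(cfg$seed)
  times <- seq(cfg$t_min, cfg$t_max, by = cfg$step)
  cons <- paste0("consumer", seq_len(cfg$n_consumers))
  jar_rows <- list(); lik_rows <- list()
  for (t in times) {
    L <- sapply(seq_len(cfg$n_attributes), function(a)
      rng$rmultinom_levels(cfg$n_consumers, cfg$level_probs[a, ], c(-1, 0, 1)))
    L <- matrix(L, cfg$n_consumers, cfg$n_attributes)
    pen <- as.numeric((L != 0) %*% cfg$penalties[cfg$attributes])
    lik <- cfg$baseline - pen + rng$rnorm(cfg$n_consumers, 0, cfg$noise_sd)
    for (a in seq_len(cfg$n_attributes))
      jar_rows[[length(jar_rows) + 1L]] <- data.frame(
        observer = cons, product = "P1", attribute = cfg$attributes[a],
        time_s = t, value = L[, a], stringsAsFactors = FALSE)
    lik_rows[[length(lik_rows) + 1L]] <- data.frame(
      observer = cons, product = "P1", attribute = "OverallLiking",
      time_s = t, value = pmin(pmax(lik, 0), 100), stringsAsFactors = FALSE)
  }
  out <- list(jar = mati_dataset(do.call(rbind, jar_rows), scale = "jar"),
              liking = mati_dataset(do.call(rbind, lik_rows), scale = "liking"))
  attr(out, "truth") <- list(
    dominant = names(which.max(cfg$penalties[cfg$attributes])),
    penalties = cfg$penalties)
  out
}

#' Generate CATA item proportions over the first bite
#'
#' Smooth logistic endorsement trajectories per item and product, sampled on
#' an integer-second grid (default 1-25 s): proportions in \[0,1\] that rise
#' or fall as the bite progresses.
#'
#' @param cfg A [sim_config()]; `n_attributes` is the item count and
#'   `attributes` the item labels. The grid defaults to 1-25 s step 1 when
#'   the config still carries the panel default (3-90).
#' @return A `mati_dataset` (scale "proportion", observer = "") with one
#'   record per product x item x time.
#' @export
gen_cata_proportions <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng <- local_rng(cfg$seed)
  times <- if (cfg$t_min == 3 && cfg$t_max == 90) seq(1, 25)
           else seq(cfg$t_min, cfg$t_max, by = cfg$step)
  prods <- paste0("P", seq_len(cfg$n_products))
  rows <- list()
  for (p in prods) for (a in cfg$attributes) {
    mid <- rng$runif(1, min(times), max(times))
    slope <- rng$runif(1, -0.5, 0.5)
    lo <- rng$runif(1, 0.02, 0.25); hi <- rng$runif(1, 0.6, 0.98)
    prop <- lo + (hi - lo) * stats::plogis(slope * (times - mid))
    rows[[length(rows) + 1L]] <- data.frame(
      observer = "", product = p, attribute = a, time_s = times,
      value = prop, stringsAsFactors = FALSE)
  }
  mati_dataset(do.call(rbind, rows), scale = "proportion")
}
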