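# Synthetic forest-inventory simulator.
#
# Generates cross-sectional (d, h) tables with the structure the estimation
# layer assumes: plots with few trees each, a Gaussian plot effect phi_i on
# alpha, diameters from a truncated normal, and heights drawn EXACTLY from
# the closed-form transition law (hd_sample), never by Euler stepping.

#' Default plot-size frequency table
#'
#' Empirical distribution of the number of height-measured trees per
#' inventory plot (1 to 14 trees) typical of national-forest-inventory Scots
#' pine plots; used as the default \code{trees_per_plot} of
#' [hd_simulate()].
#'
#' @return Named integer vector: names are plot sizes, values are plot
#'   counts.
#' @export
hd_plot_size_freq <- function() {
  c(`1` = 125L, `2` = 492L, `3` = 407L, `4` = 394L, `5` = 293L,
    `6` = 146L, `7` = 81L, `8` = 37L, `9` = 15L, `10` = 5L,
    `11` = 2L, `12` = 1L, `13` = 0L, `14` = 1L)
}

#' Default diameter distribution
#'
#' Truncated-normal law for breast-height diameters (cm) matching the
#' summary moments of the inventory data the simulator emulates.
#'
#' @param mean,sd,lower,upper moments and truncation bounds, cm.
#' @return A list with those four elements.
#' @export
hd_diameter_law <- function(mean = 27.33, sd = 8.69,
                            lower = 15.10, upper = 66.10) {
  stopifnot(sd > 0, lower < upper)
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

# inverse-CDF truncated normal (exact, no rejection)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Draw plot random effects
#'
#' i.i.d. \eqn{\phi_i \sim N(0, \sigma_\phi^2)} draws, one per plot.
#'
#' @param n_plots number of plots M.
#' @param sigma_phi random-effect standard deviation (>= 0).
#' @param seed optional integer seed.
#' @return Numeric vector of length \code{n_plots}.
#' @export
hd_draw_random_effects <- function(n_plots, sigma_phi, seed = NULL) {
  stopifnot(n_plots >= 1, sigma_phi >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n_plots, 0, sigma_phi)
}

# per-plot substream seed: adding plots never changes earlier plots
plot_seed <- function(root, i) (root + 104729 * i) %% 2147483629L

#' Simulate an inventory-style height-diameter dataset
#'
#' For each of \code{n_plots} plots: a plot effect \eqn{\phi_i \sim N(0,
#' \sigma_\phi^2)} is drawn, a plot size is drawn from
#' \code{trees_per_plot}, diameters come from the truncated-normal
#' \code{diameter} law, and each height is drawn exactly from the family's
#' closed-form transition law at its tree's diameter (see [hd_sample()]).
#' Trees are conditionally independent given \eqn{\phi_i}, matching the
#' cross-sectional estimation assumptions.  Each plot uses its own random
#' substream derived from \code{seed}, so enlarging \code{n_plots} leaves
#' earlier plots unchanged.
#'
#' @param n_plots number of plots M (>= 1).
#' @param family family code or name.
#' @param params an [hd_params()] object; its \code{sigma_phi} (0 if
#'   \code{NULL}) scales the plot effects.
#' @param trees_per_plot either a single integer (fixed plot size) or a
#'   named frequency table as from [hd_plot_size_freq()].
#' @param diameter a list as from [hd_diameter_law()].
#' @param seed integer seed; required for reproducibility.
#' @return A data frame of class \code{c("hd_data", "data.frame")} with
#'   columns \code{plot_id}, \code{tree_id}, \code{d_cm}, \code{h_m},
#'   \code{phi_true}, and the generating configuration in
#'   \code{attr(, "config")}.
#' @examples
#' p <- hd_params("V", alpha = 26.63, beta = 0.0667, sigma = 0.606,
#'                sigma_phi = 3.94)
#' sim <- hd_simulate(20, "V", p, seed = 1)
#' head(sim)
#' @export
hd_simulate <- function(n_plots, family, params,
                        trees_per_plot = hd_plot_size_freq(),
                        diameter = hd_diameter_law(),
                        seed = NULL) {
  code <- hd_family_code(family)
  p <- as_hd_params(params)
  stopifnot(n_plots >= 1)
  sp <- if (is.null(p$sigma_phi)) 0 else p$sigma_phi
  if (length(trees_per_plot) == 1L && is.null(names(trees_per_plot))) {
    sizes <- as.integer(trees_per_plot)
    if (sizes < 1L) stop("plot size must be >= 1", call. = FALSE)
    size_vals <- sizes; size_prob <- 1
  } else {
    size_vals <- as.integer(names(trees_per_plot))
    size_prob <- as.numeric(trees_per_plot)
    if (any(size_vals < 1L) || any(size_prob < 0) || sum(size_prob) <= 0)
      stop("invalid 'trees_per_plot' frequency table", call. = FALSE)
  }
  if (diameter$lower <= hd_d0(code))
    stop("diameter lower bound must exceed d0", call. = FALSE)
  root <- if (is.null(seed)) sample.int(2^31 - 2, 1) else as.integer(seed)
  out <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    set.seed(plot_seed(root, i))
    phi <- stats::rnorm(1, 0, sp)
    ni <- if (length(size_vals) == 1L) size_vals else
      sample(size_vals, 1, prob = size_prob)
    d <- rtruncnorm(ni, diameter$mean, diameter$sd,
                    diameter$lower, diameter$upper)
    h <- hd_sample(ni, code, p, d = d, phi = phi)
    out[[i]] <- data.frame(plot_id = i, tree_id = seq_len(ni),
                           d_cm = d, h_m = h, phi_true = phi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- list(n_plots = n_plots, family = code, params = p,
                              trees_per_plot = trees_per_plot,
                              diameter = diameter, seed = root)
  class(res) <- c("hd_data", class(res))
  res
}

#' Read and write height-diameter CSV files
#'
#' The on-disk format is a plain CSV with header
#' \code{plot_id,tree_id,d_cm,h_m} and an optional \code{phi_true} column.
#' \code{hd_read_csv} validates the table: missing columns, non-numeric or
#' non-positive \code{d_cm}/\code{h_m}, and duplicated \code{(plot_id,
#' tree_id)} pairs are reported with the offending row numbers.
#'
#' @param path file path.
#' @param data a data frame with the columns above.
#' @return \code{hd_read_csv}: the validated data frame (class
#'   \code{"hd_data"}); \code{hd_write_csv}: \code{path}, invisibly.
#' @export
hd_read_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  hd_validate_data(df)
}

#' @rdname hd_read_csv
#' @export
hd_write_csv <- function(data, path) {
  keep <- intersect(c("plot_id", "tree_id", "d_cm", "h_m", "phi_true"),
                    names(data))
  utils::write.csv(data[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname hd_read_csv
#' @export
hd_validate_data <- function(data) {
  need <- c("plot_id", "tree_id", "d_cm", "h_m")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("d_cm", "h_m")) {
    bad <- which(!is.finite(data[[col]]) | data[[col]] <= 0)
    if (length(bad))
      stop("non-positive or non-numeric ", col, " in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(data$plot_id, data$tree_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (plot_id, tree_id) in row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  if (!inherits(data, "hd_data")) class(data) <- c("hd_data", class(data))
  data
}
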