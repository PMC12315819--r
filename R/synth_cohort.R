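#' Parameters for a synthetic cohort
#'
#' Describes a cohort of participants with per-sample aggregate counts:
#' sample-level expected counts are Gamma-distributed around the group mean
#' (so single readouts are negative-binomial with overdispersion
#' `dispersion`), each sample is measured in 2 replicates of 6 field-level
#' Poisson readouts, and one clinical covariate (HbA1c-like) is generated
#' with a target Spearman rank correlation to the co-aggregate count via a
#' Gaussian-copula rank coupling.
#'
#' @param n_per_group samples per group (>= 2).
#' @param group_means named list: group -> c(alpha_syn = , coagg = ) mean
#'   counts per field readout.
#' @param dispersion negative-binomial size parameter theta (> 0); smaller
#'   is more overdispersed.
#' @param covariate_rank_corr target Spearman correlation between the
#'   co-aggregate count and the covariate, in [-1, 1].
#' @param covariate_name column name for the covariate.
#' @param analyte analyte type label.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 21,
                          group_means = list(
                            HC = c(alpha_syn = 20, coagg = 4),
                            PD = c(alpha_syn = 32, coagg = 12)),
                          dispersion = 5,
                          covariate_rank_corr = 0,
                          covariate_name = "HbA1c_pct",
                          analyte = c("serum_free", "L1EV"),
                          seed = 1L) {
  analyte <- match.arg(analyte)
  check_scalar_num(n_per_group, "n_per_group", lower = 2)
  if (!is.list(group_means) || is.null(names(group_means)) ||
      length(group_means) < 2)
    stop_param("group_means", "must be a named list with >= 2 groups")
  for (g in names(group_means)) {
    gm <- group_means[[g]]
    if (!is.numeric(gm) || !all(c("alpha_syn", "coagg") %in% names(gm)) ||
        any(gm < 0))
      stop_param("group_means",
                 sprintf("group %s needs nonnegative alpha_syn and coagg means", g))
  }
  check_scalar_num(dispersion, "dispersion")
  if (dispersion <= 0) stop_param("dispersion", "must be > 0")
  check_scalar_num(covariate_rank_corr, "covariate_rank_corr",
                   lower = -1, upper = 1)
  check_scalar_num(seed, "seed")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_means = group_means, dispersion = dispersion,
                 covariate_rank_corr = covariate_rank_corr,
                 covariate_name = covariate_name,
                 analyte = analyte, seed = as.integer(seed)),
            class = "cohort_params")
}

# sample-level expected readout count: Gamma mixing so that a single
# readout is NB(mu, size = theta)
draw_sample_rates <- function(n, mu, theta) {
  if (mu == 0) return(rep(0, n))
  rgamma(n, shape = theta, rate = theta / mu)
}

#' Generate a synthetic cohort table
#'
#' One row per participant sample, with per-sample counts equal to the mean
#' of 2 replicates x 6 field readouts (Poisson around the sample's latent
#' rate), and a covariate rank-coupled to the co-aggregate count at the
#' requested Spearman correlation. Identical parameters and seed give an
#' identical table.
#'
#' @param params a [cohort_params()] object.
#' @return a data.frame of class `cohort_table` with columns `sample_id`,
#'   `group`, `analyte`, `alpha_syn_count`, `coagg_count` and the covariate;
#'   the long per-readout table is attached as `attr(, "readouts")`.
#' @export
#' @examples
#' tab <- generate_cohort(cohort_params(n_per_group = 4, seed = 2))
#' table(tab$group)
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  groups <- names(params$group_means)
  n <- params$n_per_group
  with_seed(params$seed, {
    rows <- list(); reads <- list()
    for (g in groups) {
      gm <- params$group_means[[g]]
      rate_a <- draw_sample_rates(n, gm[["alpha_syn"]], params$dispersion)
      rate_c <- draw_sample_rates(n, gm[["coagg"]], params$dispersion)
      a_counts <- matrix(rpois(n * 12, rep(rate_a, each = 12)), nrow = 12)
      c_counts <- matrix(rpois(n * 12, rep(rate_c, each = 12)), nrow = 12)
      ids <- sprintf("%s_%02d", g, seq_len(n))
      rows[[g]] <- data.frame(
        sample_id = ids, group = g, analyte = params$analyte,
        alpha_syn_count = colMeans(a_counts),
        coagg_count = colMeans(c_counts),
        stringsAsFactors = FALSE)
      reads[[g]] <- data.frame(
        sample_id = rep(ids, each = 12),
        group = g,
        replicate = rep(rep(1:2, each = 6), n),
        readout = rep(rep(1:6, 2), n),
        alpha_syn_count = as.vector(a_counts),
        coagg_count = as.vector(c_counts),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    # Gaussian-copula coupling of the covariate to the coagg count ranks
    rho_s <- params$covariate_rank_corr
    rho <- 2 * sin(pi * rho_s / 6)
    nn <- nrow(tab)
    z <- qnorm((rank(tab$coagg_count, ties.method = "average") - 0.5) / nn)
    eps <- rnorm(nn)
    zc <- rho * z + sqrt(max(0, 1 - rho^2)) * eps
    # map to an HbA1c-like scale (%), mean 6, sd 1
    tab[[params$covariate_name]] <- 6 + zc
    attr(tab, "readouts") <- do.call(rbind, reads)
    class(tab) <- c("cohort_table", "data.frame")
    tab
  })
}
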