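#' Published correlation matrix of the oak trait-environment study
#'
#' The 10-variable Pearson correlation matrix (Nmass, Narea, SLA, LS, LDW,
#' TSN, TSK, TSP, MAT, MAP) over 90 *Quercus wutaishanica* trees, stored as
#' printed (two decimals, one three-decimal entry 0.064). It is the
#' sufficient statistic for every refit in this package. Positive
#' definiteness is checked at load; a rounded matrix that had gone
#' indefinite would be repaired via [nearest_psd()] with the applied delta
#' reported as an attribute.
#'
#' @return a [corr_matrix()] with `n = 90`; attribute `"min_eigenvalue"`
#'   records the smallest eigenvalue of the printed matrix and
#'   `"psd_corrected"` whether a repair was needed.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2.csv", package = "foliarsem",
                      mustWork = TRUE)
  m <- read_corr_matrix(path, n = 90)
  ev <- min(eigen(m$mat, symmetric = TRUE, only.values = TRUE)$values)
  corrected <- FALSE
  if (ev < 1e-6) {
    fixed <- nearest_psd(m)
    message("printed matrix repaired to PSD; max entry change ",
            format(attr(fixed, "max_delta"), digits = 3))
    m <- fixed
    corrected <- TRUE
  }
  attr(m, "min_eigenvalue") <- ev
  attr(m, "psd_corrected") <- corrected
  m
}

#' Published per-variable summary statistics
#'
#' Mean, standard error, minimum, maximum and CV (%) of the ten model
#' variables, as printed for the 90 sampled trees; used as rescaling
#' targets by the simulator (SD is reconstructed as mean * CV / 100).
#' The printed LDW row is internally inconsistent (minimum equals the
#' mean); it is stored as printed and flagged, never "fixed".
#'
#' @return data frame with columns `variable`, `mean`, `se`, `min`, `max`,
#'   `cv`, `sd` (reconstructed); attribute `"flagged"` names inconsistent
#'   rows.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1.csv", package = "foliarsem",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$sd <- df$mean * df$cv / 100
  # a strictly varying trait must have min < mean < max
  bad <- df$variable[df$min >= df$mean | df$max <= df$mean]
  attr(df, "flagged") <- bad
  df
}

#' Built-in model fixtures of the study
#'
#' Four ready-made [model_spec()]s:
#' \describe{
#'   \item{`nmass_final`}{final mass-based leaf N model: MAP drives TSK and
#'     TSP (correlated residuals), TSP drives the latent morphology factor
#'     LMT1 (indicators SLA, LS), and Nmass is driven by TSK and LMT1.}
#'   \item{`narea_final`}{final area-based model: same climate/soil block,
#'     latent LMT2 (indicators SLA, LDW), and Narea driven by TSK, TSP
#'     (direct) and LMT2.}
#'   \item{`prior_nmass`, `prior_narea`}{the reconstructed full prior:
#'     MAT and MAP exogenous and correlated, paths from both climate
#'     variables to every soil nutrient, to the three-indicator latent LMT
#'     (SLA, LS, LDW) and to the foliar-N outcome, paths from all three
#'     soil nutrients to LMT and to the outcome, LMT to the outcome, and
#'     free covariances among the soil-nutrient residuals. The direct
#'     climate-to-outcome paths and the MAT~~MAP covariance are a
#'     documented reconstruction choice.}
#' }
#' The same models ship as model-text files under
#' `system.file("extdata", "models", package = "foliarsem")`.
#'
#' @return named list of [model_spec()] objects.
#' @export
paper_models <- function() {
  nmass_final <- model_spec(
    paths = list(c("MAP", "TSK"), c("MAP", "TSP"), c("TSP", "LMT1"),
                 c("TSK", "Nmass"), c("LMT1", "Nmass")),
    latents = list(LMT1 = c("SLA", "LS")),
    covs = list(c("TSK", "TSP")))
  narea_final <- model_spec(
    paths = list(c("MAP", "TSK"), c("MAP", "TSP"), c("TSP", "LMT2"),
                 c("TSP", "Narea"), c("TSK", "Narea"), c("LMT2", "Narea")),
    latents = list(LMT2 = c("SLA", "LDW")),
    covs = list(c("TSK", "TSP")))
  prior <- function(outcome) model_spec(
    paths = list(
      c("MAT", "TSN"), c("MAT", "TSK"), c("MAT", "TSP"),
      c("MAP", "TSN"), c("MAP", "TSK"), c("MAP", "TSP"),
      c("MAT", "LMT"), c("MAP", "LMT"),
      c("MAT", outcome), c("MAP", outcome),
      c("TSN", "LMT"), c("TSK", "LMT"), c("TSP", "LMT"),
      c("TSN", outcome), c("TSK", outcome), c("TSP", outcome),
      c("LMT", outcome)),
    latents = list(LMT = c("SLA", "LS", "LDW")),
    covs = list(c("MAT", "MAP"), c("TSN", "TSK"), c("TSN", "TSP"),
                c("TSK", "TSP")))
  list(nmass_final = nmass_final, narea_final = narea_final,
       prior_nmass = prior("Nmass"), prior_narea = prior("Narea"))
}
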