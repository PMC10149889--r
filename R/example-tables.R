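#' Bundled correlation tables from a loneliness-measure validation study
#'
#' Loads the summary tables of a three-study psychometric validation of
#' loneliness measures that ship with the package as worked-example data:
#' convergent-validity matrices of self- and informant-ratings, the
#' self-informant agreement triangles, the nomological-net blocks
#' (correlates by measures, with domain tags), the published profile-ICC
#' matrices derived from those blocks, measure reliabilities (coefficient
#' omega for multi-item scales, three-wave retest estimates for single
#' items), and the published three-wave reliability table. Study 1 used
#' six measures rated by targets and 1-6 informants each; Study 2 used
#' four measures rated within couples; Study 3 estimated single-item
#' retest reliability over three occasions.
#'
#' @return named list: `study1` and `study2`, each with `convergent_self`,
#'   `convergent_informant` ([corr_matrix()] objects), `agreement` (self x
#'   informant matrix, unprinted upper triangle `NA`), `nomonet` (list
#'   `values` matrix + `domains` vector), `profile_icc` (published lower
#'   triangle); plus `reliabilities` (data frame) and `study3_reliability`
#'   (data frame).
#' @examples
#' tabs <- loneliness_tables()
#' matrix_mad(tabs$study1$convergent_self, tabs$study1$convergent_informant)
#' @export
loneliness_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "validnet", mustWork = TRUE)
  mat <- function(f, sym) {
    d <- utils::read.csv(path(f), check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    if (sym) corr_matrix(m, symmetric = TRUE) else m
  }
  nomo <- function(f) {
    d <- utils::read.csv(path(f), check.names = FALSE)
    vals <- as.matrix(d[, -(1:2), drop = FALSE])
    rownames(vals) <- d$correlate
    list(values = vals, domains = stats::setNames(d$domain, d$correlate))
  }
  list(
    study1 = list(
      convergent_self = mat("study1_convergent_self.csv", TRUE),
      convergent_informant = mat("study1_convergent_informant.csv", TRUE),
      agreement = mat("study1_agreement.csv", FALSE),
      nomonet = nomo("study1_nomonet.csv"),
      profile_icc = mat("study1_profile_icc.csv", FALSE)),
    study2 = list(
      convergent_self = mat("study2_convergent_self.csv", TRUE),
      convergent_informant = mat("study2_convergent_partner.csv", TRUE),
      agreement = mat("study2_agreement.csv", FALSE),
      nomonet = nomo("study2_nomonet.csv"),
      profile_icc = mat("study2_profile_icc.csv", FALSE)),
    reliabilities = utils::read.csv(path("measure_reliabilities.csv")),
    study3_reliability = utils::read.csv(path("study3_reliability.csv")))
}
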