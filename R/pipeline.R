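## Study-shaped orchestration: run the validity analyses end to end on
## synthetic or user data and emit the full table bundle plus one
## machine-readable summary.

#' Read a long rating table from delimited text
#'
#' Expects UTF-8, a header row, period decimal separator and one
#' observation per row with columns `target`, `rater`, `role`, `wave`,
#' `measure`, `score`.
#'
#' @param path file path.
#' @param sep field separator (default `,`).
#' @return validated rating table data frame.
#' @export
read_rating_table <- function(path, sep = ",") {
  check_rating_table(utils::read.table(path, header = TRUE, sep = sep,
                                       stringsAsFactors = FALSE))
}

#' Read a run configuration from YAML
#'
#' A run configuration holds either input paths (`ratings`, `correlates`,
#' `reliabilities`) or a `synthetic` block with [latent_spec()] /
#' [simplex_spec()] fields, plus analysis toggles and thresholds. Exactly
#' one of the two input forms must be present.
#'
#' @param path YAML file path.
#' @return the configuration list, checked for that exclusivity.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  has_files <- !is.null(cfg$ratings)
  has_synth <- !is.null(cfg$synthetic)
  if (has_files == has_synth) {
    stop("config must contain exactly one of: input paths, synthetic spec")
  }
  cfg
}

write_table_csv <- function(df, dir, name) {
  if (is.matrix(df)) df <- data.frame(label = rownames(df), df, check.names = FALSE)
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run a complete validity study
#'
#' Orchestrates the analysis stages of a multi-measure validity study on
#' either synthetic data (a [latent_spec()]) or user data (a long rating
#' table plus a correlate table): convergent-validity matrices for self-
#' and informant-ratings with their comparison statistics, self-informant
#' agreement (cross-correlation matrix, per-measure summary, rater
#' consensus ICCs), the nomological-net block with per-domain average
#' absolute correlations, and the profile-similarity matrix over measures.
#' Deterministic given the spec's seed.
#'
#' @param spec a [latent_spec()], or a list with elements `ratings` (long
#'   rating table), `correlates` (wide per-target table, optional) and
#'   `domains` (named map, optional).
#' @param analyses subset of `c("convergent", "agreement", "nomonet",
#'   "profiles")`.
#' @param reliabilities optional data frame (`measure`, `rel_self`,
#'   `rel_informant`) enabling disattenuated agreement.
#' @param alpha_flags significance thresholds for the nomological block.
#' @param output_dir optional directory; when given, every table is written
#'   as CSV and a nested machine-readable summary as `summary.json`.
#' @return (invisibly, when writing) a named list of result objects.
#' @export
run_validity_study <- function(spec,
                               analyses = c("convergent", "agreement",
                                            "nomonet", "profiles"),
                               reliabilities = NULL,
                               alpha_flags = c(0.01, 0.001),
                               output_dir = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (inherits(spec, "latent_spec")) {
    drawn <- sample_ratings(spec)
    ratings <- drawn$ratings
    correlates <- drawn$correlates
    domains <- NULL
  } else {
    ratings <- check_rating_table(spec$ratings)
    correlates <- spec$correlates
    domains <- spec$domains
  }
  miss <- setdiff(c("self", "informant"), unique(ratings$role))
  if ("agreement" %in% analyses && "informant" %in% miss) {
    stop("agreement analysis requested but no informant ratings present")
  }
  self_wide <- ratings_to_wide(ratings, "self")
  out <- list()

  if ("convergent" %in% analyses) {
    cm_self <- pairwise_correlations(self_wide[, -1, drop = FALSE])
    out$convergent_self <- cm_self
    if (!"informant" %in% miss) {
      inf_wide <- ratings_to_wide(ratings, "informant")
      cm_inf <- pairwise_correlations(inf_wide[, -1, drop = FALSE])
      out$convergent_informant <- cm_inf
      n_self <- round(stats::median(cm_self$pair_n[lower.tri(cm_self$pair_n)]))
      n_inf <- round(stats::median(cm_inf$pair_n[lower.tri(cm_inf$pair_n)]))
      out$convergent_comparison <- matrix_equality_test(cm_self, n_self, cm_inf, n_inf)
      out$convergent_profile_icc <- matrix_profile_similarity(cm_self, cm_inf)
    }
  }

  if ("agreement" %in% analyses && !"informant" %in% miss) {
    inf_wide <- ratings_to_wide(ratings, "informant")
    out$agreement_matrix <- self_informant_matrix(self_wide, inf_wide)
    out$agreement_summary <- agreement_summary(self_wide, inf_wide, reliabilities)
    inf_long <- ratings[ratings$role == "informant", ]
    out$consensus <- do.call(rbind, lapply(unique(inf_long$measure), function(m) {
      x <- inf_long[inf_long$measure == m, ]
      ic <- consensus_icc(x$score, x$target)
      data.frame(measure = m, icc1 = ic$icc1, icc1k = ic$icc1k,
                 n_targets = ic$n_targets,
                 mean_raters_per_target = ic$mean_raters_per_target)
    }))
  }

  if (("nomonet" %in% analyses || "profiles" %in% analyses) && !is.null(correlates)) {
    block <- correlate_block(self_wide, correlates, domains, alpha_flags)
    if ("nomonet" %in% analyses) {
      out$nomonet_block <- block
      out$nomonet_averages <- block_average(block)
    }
    if ("profiles" %in% analyses) {
      if (nrow(block$values) >= 3) {
        out$profile_matrix <- profile_matrix(block)
      } else {
        warning("profile similarity skipped: fewer than 3 correlates")
      }
    }
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$convergent_self)) {
      write_table_csv(out$convergent_self$values, output_dir, "convergent_self")
    }
    if (!is.null(out$convergent_informant)) {
      write_table_csv(out$convergent_informant$values, output_dir, "convergent_informant")
    }
    if (!is.null(out$agreement_matrix)) {
      write_table_csv(out$agreement_matrix$values, output_dir, "agreement_matrix")
    }
    if (!is.null(out$agreement_summary)) {
      write_table_csv(out$agreement_summary, output_dir, "agreement_summary")
    }
    if (!is.null(out$consensus)) write_table_csv(out$consensus, output_dir, "consensus_icc")
    if (!is.null(out$nomonet_block)) {
      write_table_csv(out$nomonet_block$values, output_dir, "nomonet_block")
      write_table_csv(out$nomonet_averages, output_dir, "nomonet_averages")
    }
    if (!is.null(out$profile_matrix)) {
      write_table_csv(out$profile_matrix$icc, output_dir, "profile_matrix")
    }
    jsonlite::write_json(summarize_run(out),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

## flatten the result bundle into plain lists for the JSON summary
summarize_run <- function(out) {
  take <- function(x) {
    if (inherits(x, "corr_matrix")) {
      list(values = as.data.frame(x$values), pair_n = as.data.frame(x$pair_n))
    } else if (inherits(x, "matrix_comparison")) {
      unclass(x)
    } else if (inherits(x, "nomological_block")) {
      list(values = as.data.frame(x$values), pair_n = as.data.frame(x$pair_n),
           domains = as.list(x$domains))
    } else if (is.matrix(x)) {
      as.data.frame(x)
    } else if (is.list(x) && !is.null(x$icc)) {
      list(icc = as.data.frame(x$icc), pairs_n = as.data.frame(x$pairs_n))
    } else x
  }
  lapply(out, take)
}

#' Run a three-wave single-item reliability study
#'
#' Estimates the quasi-simplex reliability of a three-wave score table (or
#' of data drawn from a [simplex_spec()]) for the full sample (pairwise
#' deletion per lag) and for the panel subsample observed at all waves.
#'
#' @param spec a [simplex_spec()] or a wide three-wave table (`subject`,
#'   three wave columns).
#' @param level confidence level for the propagated bounds.
#' @param output_dir optional directory for the CSV/JSON bundle.
#' @return list with `full` and `panel` [heise_with_bounds()] estimates and
#'   the analyzed `waves` table.
#' @export
run_heise_study <- function(spec, level = 0.95, output_dir = NULL) {
  waves <- if (inherits(spec, "simplex_spec")) sample_three_wave(spec) else spec
  w <- waves[, setdiff(colnames(waves), "subject"), drop = FALSE]
  out <- list(full = heise_with_bounds(w, level, sample = "full"),
              panel = heise_with_bounds(w, level, sample = "panel"),
              waves = waves)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- do.call(rbind, lapply(c("full", "panel"), function(s) {
      e <- out[[s]]
      data.frame(sample = s, rxx = e$rxx, lower = e$lower, upper = e$upper,
                 r12 = e$r12, r23 = e$r23, r13 = e$r13,
                 n12 = e$n12, n23 = e$n23, n13 = e$n13)
    }))
    write_table_csv(tab, output_dir, "heise_reliability")
    jsonlite::write_json(lapply(out[c("full", "panel")], unclass),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
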