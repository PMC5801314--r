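#' Run the full synthetic decay study once
#'
#' End-to-end chain on one simulated cohort: simulate subjects and their
#' trial-level epochs, process them into fronto-central difference waves,
#' apply two-stage group-anchored MMN scoring, form the short-minus-long ISI
#' decay score (duration deviant), apply the positive-outlier exclusion rule
#' to the long-ISI scores, build the PCA composite scores from the battery,
#' and assemble the per-subject analysis table.
#'
#' @param config A [simulation_config()].
#' @param families_opt1 Optimum-1 deviant families to simulate and score
#'   (`"duration"` suffices for the decay score; all five for the complete
#'   study).
#' @param filter_stage Passed to [process_subject()]; `"average"` (default)
#'   is the fast linear-equivalent path, `"trial"` filters every trial.
#' @param p2p_limit_uv Artifact rejection limit, microvolts.
#' @return List: `cohort`, `scores` (long per-subject scores with group and
#'   exclusion flag), `delta` (duration-deviant decay scores), `excluded`
#'   (subject ids removed by the outlier rule), `weights`
#'   (`composite_weights`), `component_labels`, `analysis` (wide per-subject
#'   data frame of composites, decay score and covariates, outliers removed),
#'   `rejection` (mean rejected-trial fraction).
#' @export
run_decay_study <- function(config = simulation_config(),
                            families_opt1 = "duration",
                            filter_stage = "average",
                            p2p_limit_uv = 100) {
  cohort <- simulate_cohort(config)
  waves <- list(opt1 = list(), memtra = list())
  rej <- c()
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    attr(subj, "config") <- config
    for (par in c("opt1", "memtra")) {
      conds <- c("standard",
                 if (par == "opt1") families_opt1 else c("duration", "frequency"))
      ep <- simulate_epochs(subj, par, config, conditions = conds)
      pr <- process_subject(ep, p2p_limit_uv = p2p_limit_uv,
                            filter_stage = filter_stage)
      for (f in setdiff(conds, "standard"))
        waves[[par]][[f]][[subj$subject_id]] <- pr$difference[[f]]
      rej <- c(rej, vapply(pr$reports, `[[`, 0, "fraction_rejected"))
    }
  }
  groups <- stats::setNames(as.character(cohort$group), cohort$subject_id)

  scores <- do.call(rbind, unlist(lapply(names(waves), function(par)
    lapply(names(waves[[par]]), function(f)
      score_cohort(waves[[par]][[f]], groups, family = f))),
    recursive = FALSE))
  rownames(scores) <- NULL

  mem_scores <- scores[scores$paradigm == "memtra", ]
  outl <- flag_positive_outliers(mem_scores)
  scores$excluded <- scores$subject_id %in% outl$excluded

  opt_dur <- scores[scores$paradigm == "opt1" & scores$family == "duration", ]
  mem_dur <- scores[scores$paradigm == "memtra" & scores$family == "duration", ]
  both <- intersect(opt_dur$subject_id, mem_dur$subject_id)
  delta <- do.call(rbind, lapply(both, function(id)
    delta_mmn(opt_dur[opt_dur$subject_id == id, ],
              mem_dur[mem_dur$subject_id == id, ])))

  bat <- cohort[, battery_layout()$variable]
  rownames(bat) <- cohort$subject_id
  zs <- zstandardize(bat)
  weights <- extract_components(zs$z)
  comps <- build_composites(zs$z, weights)
  labels <- label_components(weights)

  analysis <- data.frame(subject_id = cohort$subject_id,
                         group = cohort$group,
                         age_years = cohort$age_years,
                         education_years = cohort$education_years,
                         stringsAsFactors = FALSE)
  for (j in colnames(comps)) {
    nm <- if (!is.na(labels[j]) && labels[j] == "memory") "memory_cs"
          else if (!is.na(labels[j]) && labels[j] == "ef") "ef_cs" else j
    analysis[[nm]] <- comps[analysis$subject_id, j]
  }
  analysis$delta_mmn_dur <- delta$delta_uv[match(analysis$subject_id,
                                                 delta$subject_id)]
  analysis$opt1_dur_uv <- opt_dur$amplitude_uv[match(analysis$subject_id,
                                                     opt_dur$subject_id)]
  analysis$memtra_dur_uv <- mem_dur$amplitude_uv[match(analysis$subject_id,
                                                       mem_dur$subject_id)]
  analysis$true_delta_uv <- cohort$true_delta_uv
  analysis <- analysis[!analysis$subject_id %in% outl$excluded, ]

  list(cohort = cohort, scores = scores, delta = delta,
       excluded = outl$excluded, weights = weights, z_params = zs$params,
       component_labels = labels, analysis = analysis,
       rejection = mean(rej))
}
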