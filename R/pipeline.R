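#' Study configuration for the validation pipeline
#'
#' MCMC settings default to the full analysis scale (50k burnin / 250k
#' steps / 5 runs); pass smaller values for desk-scale work.
#'
#' @param models admixture model variants to run.
#' @param thresholds ancestry thresholds for hybrid calls.
#' @param per_class_n simulated individuals per hybrid class.
#' @param n_ref reference pure individuals per species.
#' @param q_cut reference-selection ancestry cut-off.
#' @param burnin,steps,thin,n_runs MCMC schedule for all samplers.
#' @param prelim_burnin,prelim_steps schedule of the preliminary
#'   reference-selection run.
#' @param nh_prior allele-frequency prior of the six-class sampler.
#' @param pure_band pure reference band for the interval non-overlap rule.
#' @param seed master seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(models = c("i", "ii", "iii", "iv"),
                         thresholds = c(0.1, 0.2),
                         per_class_n = 80, n_ref = 80, q_cut = 0.9,
                         burnin = 50000, steps = 250000, thin = 10, n_runs = 5,
                         prelim_burnin = burnin, prelim_steps = steps,
                         nh_prior = "jeffreys", pure_band = 0.05, seed = 1234) {
  structure(as.list(environment()), class = "study_config")
}

## preliminary strict-assignment run (no admixture, independent frequencies)
prelim_ancestry <- function(table, config) {
  spec <- admixture_spec(admixture = FALSE, correlated = FALSE,
                         burnin = config$prelim_burnin, steps = config$prelim_steps,
                         thin = config$thin, n_runs = min(config$n_runs, 2),
                         seed = config$seed)
  run_admixture(table, spec)
}

#' A priori simulation study: per-class assignment accuracy
#'
#' Selects reference pure individuals from a preliminary strict-assignment
#' run, builds a panel of simulated hybrids from the reference allele
#' frequencies, runs all requested admixture model variants and the
#' six-class sampler on the panel, and scores the percentage of correct
#' assignments per class, method and threshold. "Correct" means: for pure
#' classes, not called admixed (admixture models) or MAP pure class
#' (six-class); for hybrid classes, called admixed at the threshold, or MAP
#' equal to the true class.
#'
#' @param table an [msat_table()] with pure individuals to draw references
#'   from.
#' @param config a [study_config()].
#' @param ancestry optional precomputed preliminary ancestry (skips the
#'   reference-selection run).
#' @return list of class `simulation_study`: `accuracy` (data frame),
#'   `panel`, `ancestries` (per model), `nh`, `config`.
#' @export
simulation_study <- function(table, config = study_config(), ancestry = NULL) {
  if (is.null(ancestry)) ancestry <- prelim_ancestry(table, config)
  pan <- build_panel(table, ancestry, per_class_n = config$per_class_n,
                     n_ref = config$n_ref, q_cut = config$q_cut,
                     seed = config$seed)
  panel <- pan$panel
  cls <- panel$truth$hybrid_class
  is_pure <- cls %in% c("PureA", "PureB")

  acc <- list()
  ancestries <- list()
  for (m in config$models) {
    spec <- model_variant(m, burnin = config$burnin, steps = config$steps,
                          thin = config$thin, n_runs = config$n_runs,
                          seed = config$seed + match(m, c("i", "ii", "iii", "iv")) * 1000)
    anc <- run_admixture(panel, spec)
    ancestries[[m]] <- anc
    calls <- classify_hybrids(anc, thresholds = config$thresholds,
                              pure_band = config$pure_band)
    for (t in config$thresholds) {
      flag <- calls[[sprintf("admixed_q%g", t)]]
      for (cl in unique(cls)) {
        sel <- cls == cl
        correct <- if (cl %in% c("PureA", "PureB")) !flag[sel] else flag[sel]
        acc[[length(acc) + 1L]] <- data.frame(
          class = cl, method = paste0("model_", m), threshold = t,
          pct_correct = 100 * mean(correct), n = sum(sel),
          stringsAsFactors = FALSE)
      }
    }
  }

  nh <- run_newhybrids(panel, newhybrids_spec(prior = config$nh_prior,
                                              burnin = config$burnin,
                                              steps = config$steps,
                                              thin = config$thin,
                                              n_runs = config$n_runs,
                                              seed = config$seed + 9000))
  for (cl in unique(cls)) {
    sel <- cls == cl
    acc[[length(acc) + 1L]] <- data.frame(
      class = cl, method = "six_class", threshold = 0.5,
      pct_correct = 100 * mean(nh$map[sel] == cl), n = sum(sel),
      stringsAsFactors = FALSE)
  }
  structure(list(accuracy = do.call(rbind, acc), panel = panel,
                 ancestries = ancestries, nh = nh, config = config),
            class = "simulation_study")
}

#' Assign individuals to species by mtDNA haplotype
#'
#' Nearest-pool assignment: each control-region sequence is compared to the
#' profile's species haplotype pools and assigned to the species with the
#' smaller minimum Hamming distance (pairwise deletion of N/gaps).
#'
#' @param cr a [seq_alignment()] of control-region sequences.
#' @param profile the [make_profile()] whose pools to use.
#' @return named character vector (`"A"`/`"B"`) per record.
#' @export
assign_mtdna_species <- function(cr, profile) {
  pool_mats <- lapply(profile$mtdna, function(p)
    do.call(rbind, strsplit(p$haplotypes, "")))
  vapply(cr$sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    dmin <- vapply(pool_mats, function(pm) {
      min(apply(pm, 1, function(h) {
        use <- ch %in% c("A", "C", "G", "T") & h %in% c("A", "C", "G", "T")
        if (!sum(use)) Inf else sum(ch[use] != h[use])
      }))
    }, numeric(1))
    names(dmin)[which.min(dmin)]
  }, character(1))
}

## per-individual call table across models/thresholds (Table-3-like layout)
build_call_table <- function(ancestries, nh, thresholds, pure_band,
                             mtdna_species = NULL) {
  ids <- rownames(ancestries[[1]]$q)
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$mtdna <- if (is.null(mtdna_species)) NA_character_ else mtdna_species[ids]
  flag_cols <- character(0)
  retained_any <- rep(FALSE, length(ids))
  for (m in names(ancestries)) {
    calls <- classify_hybrids(ancestries[[m]], thresholds = thresholds,
                              pure_band = pure_band)
    for (t in thresholds) {
      col <- sprintf("model_%s_q%g", m, t)
      out[[col]] <- calls[[sprintf("admixed_q%g", t)]]
      flag_cols <- c(flag_cols, col)
    }
    retained_any <- retained_any | calls$retained
  }
  if (!is.null(nh)) {
    out$six_class <- nh$map
    out$six_class_hybrid <- nh$is_hybrid
    flag_cols <- c(flag_cols, "six_class_hybrid")
  }
  out$consensus <- rowSums(as.matrix(out[flag_cols]))
  out$retained <- retained_any & out$consensus > 0
  attr(out, "flag_cols") <- flag_cols
  out
}

#' Empirical hybrid scan over locus panels
#'
#' Runs the assignment models over one or more locus panels (typically the
#' full panel, the panel without high-null-allele loci, and the panel without
#' the diagnostic/outlier loci) and tabulates per-individual hybrid calls
#' with consensus counts and the interval non-overlap rule.
#'
#' @param table an [msat_table()].
#' @param panels named list of locus-name vectors; `NULL` builds the default
#'   three panels data-driven: `p9` = all loci; `p8` = loci whose estimated
#'   null-allele frequency is below `nal_cut` in every species; `p6` = `p8`
#'   minus `outlier_loci`.
#' @param config a [study_config()]; `config$models` is used for every panel.
#' @param mtdna_species optional named species vector from
#'   [assign_mtdna_species()].
#' @param nal_cut null-allele threshold for the reduced panel (default 0.15).
#' @param outlier_loci loci treated as under selection/diagnostic (default
#'   the three known names intersected with the table's loci).
#' @param run_nh run the six-class sampler per panel (default TRUE).
#' @return list of class `empirical_scan`: `calls` (per-panel data frames),
#'   `summary` (per-panel counts: flagged by >= 1, >= 2, all models;
#'   retained), `panels`.
#' @export
empirical_scan <- function(table, panels = NULL, config = study_config(),
                           mtdna_species = NULL, nal_cut = 0.15,
                           outlier_loci = c("MP318", "MP8450", "Mmerhk-3b"),
                           run_nh = TRUE) {
  if (is.null(panels)) {
    sp <- table$metadata$species
    high_nal <- vapply(table$loci, function(l) {
      any(vapply(c("A", "B"), function(s) {
        rows <- which(sp == s)
        if (!length(rows)) return(FALSE)
        em <- null_allele_em(table, l, rows = rows)
        !is.na(em$null_freq) && em$null_freq > nal_cut
      }, logical(1)))
    }, logical(1))
    p8 <- table$loci[!high_nal]
    p6 <- setdiff(p8, outlier_loci)
    panels <- list(p9 = table$loci, p8 = p8, p6 = p6)
  }
  calls <- list(); summaries <- list()
  for (pn in names(panels)) {
    sub <- subset_loci(table, keep = panels[[pn]])
    ancestries <- list()
    for (m in config$models) {
      spec <- model_variant(m, burnin = config$burnin, steps = config$steps,
                            thin = config$thin, n_runs = config$n_runs,
                            seed = config$seed + match(m, c("i", "ii", "iii", "iv")) * 1000)
      ancestries[[m]] <- run_admixture(sub, spec)
    }
    nh <- NULL
    if (run_nh) {
      nh <- run_newhybrids(sub, newhybrids_spec(prior = config$nh_prior,
                                                burnin = config$burnin,
                                                steps = config$steps,
                                                thin = config$thin,
                                                n_runs = config$n_runs,
                                                seed = config$seed + 9000))
    }
    ct <- build_call_table(ancestries, nh, config$thresholds, config$pure_band,
                           mtdna_species)
    calls[[pn]] <- ct
    nflags <- length(attr(ct, "flag_cols"))
    summaries[[pn]] <- data.frame(
      panel = pn, n_loci = length(panels[[pn]]),
      flagged_any = sum(ct$consensus >= 1),
      flagged_2plus = sum(ct$consensus >= 2),
      flagged_all = sum(ct$consensus == nflags),
      retained = sum(ct$retained),
      stringsAsFactors = FALSE)
  }
  structure(list(calls = calls, summary = do.call(rbind, summaries),
                 panels = panels, config = config),
            class = "empirical_scan")
}

#' Reconcile field labels, nuclear assignment and mtDNA assignment
#'
#' Three-way reconciliation: when nuclear and mtDNA assignments agree with
#' each other but contradict the field label, the individual is a field
#' mislabel (relabelled); when nuclear and mtDNA conflict, the individual is
#' a true mito-nuclear discordance retained for verification.
#'
#' @param nuclear_species named character vector (`"A"`/`"B"`) of nuclear
#'   assignments (e.g. majority ancestry cluster).
#' @param mtdna_species named character vector of mtDNA assignments.
#' @param field_labels named character vector of field species labels.
#' @return data frame per individual: `id`, `field`, `nuclear`, `mtdna`,
#'   `status` in {"concordant", "field mislabel", "discordant"}.
#' @export
mitonuclear_discordance <- function(nuclear_species, mtdna_species, field_labels) {
  ids <- names(nuclear_species)
  if (is.null(ids)) stop("nuclear_species must be named by individual ID")
  nuc <- nuclear_species[ids]
  mt <- mtdna_species[ids]
  fl <- field_labels[ids]
  status <- ifelse(nuc != mt, "discordant",
                   ifelse(nuc == fl, "concordant", "field mislabel"))
  data.frame(id = ids, field = unname(fl), nuclear = unname(nuc),
             mtdna = unname(mt), status = unname(status),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Majority-cluster nuclear species assignment
#' @param ancestry an `ancestry_result` with cluster 1 oriented to species A.
#' @return named character vector.
#' @export
nuclear_species <- function(ancestry) {
  stats::setNames(ifelse(ancestry$q[, 1] >= 0.5, "A", "B"), rownames(ancestry$q))
}
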