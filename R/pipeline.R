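#' @name pipeline
#' @title End-to-end analysis orchestration
#' @description Runs the full chain in dependency order: polarization ->
#'   derived allele frequencies -> windowed F_ST scan -> outlier-region
#'   merging -> modal-tract detection and inversion genotyping ->
#'   variant-effect/concordance checks -> population summary statistics
#'   -> expression-specificity enrichment. Stage outputs can be cached
#'   on disk keyed by an md5 digest of their inputs, so unchanged
#'   reruns are read back instead of recomputed.
NULL

.stage <- function(cache_dir, name, inputs, fun) {
  dg <- object_digest(inputs)
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, sprintf("stage-%s-%s.rds", name, dg))
    if (file.exists(f)) {
      return(list(value = readRDS(f), digest = dg, cached = TRUE))
    }
    v <- fun()
    saveRDS(v, f)
    return(list(value = v, digest = dg, cached = FALSE))
  }
  list(value = fun(), digest = dg, cached = FALSE)
}

# union of outlier regions across comparisons, per scaffold
.dedup_regions <- function(outliers) {
  all <- do.call(rbind, outliers)
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (scaf in unique(all$scaffold)) {
    d <- all[all$scaffold == scaf, ]
    red <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    out[[scaf]] <- data.frame(scaffold = scaf,
                              start = IRanges::start(red) - 1,
                              end = IRanges::end(red), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full analysis chain
#'
#' @param x a [sim_config()] (the dataset is simulated first) or an
#'   existing `hs_dataset`.
#' @param out_dir optional directory for cached stage outputs and the
#'   rendered report.
#' @param window,step,fst_threshold F_ST scan parameters.
#' @param min_span,min_modal_fraction tract-detector parameters.
#' @param exclude_from_structure extra scaffolds (beyond the Z) dropped
#'   from the genotype PCA, e.g. an inversion scaffold for
#'   leave-one-out clustering checks.
#' @return object of class `hs_run`: `manifest`, `dataset`,
#'   `decisions`, `ancestral_counts`, `fst`, `tracts`, `calls`,
#'   `concordance`, `popstats`, `expression`, `pca`.
#' @export
run_full <- function(x, out_dir = NULL, window = 10000, step = 5000,
                     fst_threshold = 0.5, min_span = 1e5,
                     min_modal_fraction = 0.6,
                     exclude_from_structure = character(0)) {
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  note <- function(name, st) {
    stages[[name]] <<- data.frame(stage = name, digest = st$digest,
                                  cached = st$cached, stringsAsFactors = FALSE)
    st$value
  }

  if (inherits(x, "sim_config")) {
    ds <- note("simulate", .stage(out_dir, "simulate", x,
                                  function() simulate_dataset(x)))
  } else if (inherits(x, "hs_dataset")) {
    ds <- x
  } else stop("x must be a sim_config or an hs_dataset")

  decisions <- note("polarize", .stage(out_dir, "polarize",
                                       list(ds$sites, ds$outgroup),
                                       function() polarize_sites(ds$sites, ds$outgroup)))
  anc <- note("ancestral", .stage(out_dir, "ancestral",
                                  list(decisions, names(ds$ref)),
                                  function() build_ancestral_reference(ds$ref, decisions)))
  freqs <- note("frequencies", .stage(out_dir, "frequencies",
                                      list(decisions, dim(ds$geno)),
                                      function() population_frequencies(ds, decisions)))
  scan <- note("fst_scan", .stage(out_dir, "fst_scan",
                                  list(decisions, window, step, fst_threshold),
                                  function() fst_scan(ds, decisions, window, step,
                                                      fst_threshold)))

  # --- tract detection and genotyping, per population and scaffold
  detect_all <- function() {
    pl <- ploidy_matrix(ds)
    pops <- unique(ds$samples$population)
    tracts <- list(); calls <- list()
    for (pn in pops) {
      cols <- which(ds$samples$population == pn)
      fq <- freqs[[pn]]
      for (si in seq_len(nrow(ds$scaffolds))) {
        scaf <- ds$scaffolds$name[si]
        rows <- which(ds$sites$scaffold == scaf)
        T <- sum(pl[rows[1], cols])
        if (T < 4) next
        tr <- detect_tracts(fq[rows, ], T, min_span = min_span,
                            min_modal_fraction = min_modal_fraction,
                            population = pn)
        if (nrow(tr) == 0) next
        tracts[[length(tracts) + 1]] <- tr
        dd <- derived_dosage(ds$geno, decisions, pl)
        for (ti in seq_len(nrow(tr))) {
          cl <- genotype_samples(tr[ti, ], fq, dd[, cols, drop = FALSE],
                                 ds$sites, pl[rows[1], cols])
          calls[[length(calls) + 1]] <- cl
        }
      }
    }
    list(tracts = do.call(rbind, tracts), calls = calls)
  }
  inv <- note("inversions", .stage(out_dir, "inversions",
                                   list(decisions, min_span, min_modal_fraction),
                                   detect_all))

  # --- effect annotation of coding SNPs; stop-loss concordance
  effects_all <- function() {
    cds_key <- paste(ds$degeneracy$genome$scaffold, ds$degeneracy$genome$pos)
    in_cds <- paste(ds$sites$scaffold, ds$sites$pos) %in% cds_key
    annotate_effect(ds$sites[in_cds, , drop = FALSE], ds$genes, ds$ref)
  }
  if (is.null(ds$degeneracy)) ds$degeneracy <- classify_degeneracy(ds$genes, ds$ref)
  effects <- note("effects", .stage(out_dir, "effects", list(dim(ds$sites)),
                                    effects_all))

  conc <- list()
  stop_sites <- effects[effects$effect == "stop_loss", , drop = FALSE]
  if (nrow(stop_sites) && length(inv$calls)) {
    pl <- ploidy_matrix(ds)
    dd <- derived_dosage(ds$geno, decisions, pl)
    for (k in seq_len(nrow(stop_sites))) {
      srow <- which(ds$sites$scaffold == stop_sites$scaffold[k] &
                      ds$sites$pos == stop_sites$pos[k])
      for (cl in inv$calls) {
        tr <- cl$tract
        if (tr$scaffold == stop_sites$scaffold[k] &&
            stop_sites$pos[k] > tr$start && stop_sites$pos[k] <= tr$end) {
          cols <- match(names(cl$genotype), colnames(dd))
          conc[[length(conc) + 1]] <- list(
            site = stop_sites[k, c("scaffold", "pos", "gene_id")],
            population = tr$population,
            concordance = concordance(cl, dd[srow, cols], pl[srow, cols]),
            inversion_frequency = cl$frequency,
            variant_frequency = sum(dd[srow, cols], na.rm = TRUE) /
              sum(pl[srow, cols][!is.na(dd[srow, cols])]))
        }
      }
    }
  }

  # --- population summary statistics (autosomes, Table-3 style block)
  popstats_all <- function() {
    auto <- ds$scaffolds$name[!ds$scaffolds$is_z]
    gmap <- ds$degeneracy$genome
    class_sites <- table(gmap$class[gmap$scaffold %in% auto])
    out <- list()
    for (pn in unique(ds$samples$population)) {
      fq <- freqs[[pn]]
      keep <- fq$scaffold %in% auto & !is.na(fq$freq)
      n <- max(fq$n_chrom[keep])
      keep <- keep & fq$n_chrom == n           # complete-case sites
      key <- paste(fq$scaffold, fq$pos)[keep]
      cls <- gmap$class[match(key, paste(gmap$scaffold, gmap$pos))]
      k <- round(fq$freq[keep] * n)
      res <- list()
      for (dc in c("zero_fold", "four_fold")) {
        sel <- !is.na(cls) & cls == dc
        res[[dc]] <- pi_and_tajimas_d(k[sel], n,
                                      n_sites = as.integer(class_sites[dc]))
      }
      seg <- fq$freq > 0 & fq$freq < 1 & !is.na(fq$freq)
      seg_key <- paste(fq$scaffold, fq$pos)[seg]
      eff_pop <- effects[paste(effects$scaffold, effects$pos) %in% seg_key, ]
      gp <- gene_polymorphism(eff_pop, ds$degeneracy)
      out[[pn]] <- list(n_chromosomes = n,
                        pi0 = res$zero_fold$pi, pi4 = res$four_fold$pi,
                        D0 = res$zero_fold$D, D4 = res$four_fold$D,
                        S0 = res$zero_fold$S, S4 = res$four_fold$S,
                        pN = gp$medians$pN, pS = gp$medians$pS,
                        pNpS = gp$medians$pNpS)
    }
    out
  }
  pstats <- note("popstats", .stage(out_dir, "popstats", list(dim(ds$geno)),
                                    popstats_all))

  # --- expression specificity and regional enrichment
  expr_all <- function() {
    regions <- .dedup_regions(scan$outliers)
    profiles <- lapply(.SPM_DIMENSIONS, function(dm)
      compute_spm(ds$expr, ds$expr_design, dm))
    names(profiles) <- .SPM_DIMENSIONS
    enr <- list()
    for (ri in seq_len(nrow(regions))) {
      for (dm in .SPM_DIMENSIONS) {
        cnt <- region_class_counts(profiles[[dm]]$label, ds$genes$genes,
                                   regions[ri, , drop = FALSE])
        lab <- sprintf("%s:%d-%d:%s", regions$scaffold[ri], regions$start[ri],
                       regions$end[ri], dm)
        enr[[lab]] <- tryCatch(
          c(enrichment_test(cnt$inside, cnt$outside)[c("statistic", "df", "p_value")],
            list(n_inside = sum(cnt$inside))),
          error = function(e) list(error = conditionMessage(e)))
      }
    }
    list(regions = regions, profiles = profiles, enrichment = enr)
  }
  expro <- note("expression", .stage(out_dir, "expression", list(dim(ds$expr)),
                                     expr_all))

  # --- genotype PCA (Z excluded; optional extra exclusions)
  z_scafs <- ds$scaffolds$name[ds$scaffolds$is_z]
  pca <- genotype_pca(ds$geno, ds$sites,
                      exclude = c(z_scafs, exclude_from_structure))

  manifest <- list(
    package = as.character(utils::packageVersion("hornscan")),
    parameters = list(window = window, step = step,
                      fst_threshold = fst_threshold, min_span = min_span,
                      min_modal_fraction = min_modal_fraction,
                      exclude_from_structure = exclude_from_structure),
    config = if (inherits(x, "sim_config")) x else NULL,
    stages = do.call(rbind, stages))

  structure(list(manifest = manifest, dataset = ds, decisions = decisions,
                 ancestral_counts = anc$counts, fst = scan,
                 tracts = inv$tracts, calls = inv$calls, effects = effects,
                 concordance = conc, popstats = pstats, expression = expro,
                 pca = pca),
            class = "hs_run")
}

#' Render a run report
#'
#' @param run an `hs_run` from [run_full()].
#' @param json_path optional path; the machine-readable summary is
#'   written there as JSON.
#' @return list with `text` (character lines) and `summary` (list
#'   serialized to JSON).
#' @export
report_render <- function(run, json_path = NULL) {
  L <- character(0)
  add <- function(...) L <<- c(L, sprintf(...))
  add("== hornscan run report ==")
  add("polarization: %d updated, %d masked, %d unchanged",
      run$ancestral_counts$updated, run$ancestral_counts$masked,
      run$ancestral_counts$unchanged)
  add("-- genome-wide F_ST (Z excluded) --")
  for (pr in names(run$fst$genome_wide)) {
    add("  %s: %.4f", pr, run$fst$genome_wide[[pr]])
  }
  add("-- outlier regions (F_ST > threshold) --")
  any_out <- FALSE
  for (pr in names(run$fst$outliers)) {
    o <- run$fst$outliers[[pr]]
    for (i in seq_len(nrow(o))) {
      any_out <- TRUE
      add("  %s %s:[%d,%d) peak %.3f (%d windows)", pr, o$scaffold[i],
          o$start[i], o$end[i], o$peak_fst[i], o$n_windows[i])
    }
  }
  if (!any_out) add("  none")
  add("-- inversion calls --")
  if (length(run$calls) == 0) add("  none") else for (cl in run$calls) {
    tb <- table(cl$genotype)
    add("  %s %s:[%d,%d) modal %s; genotypes %s; frequency %s",
        cl$tract$population, cl$tract$scaffold, cl$tract$start, cl$tract$end,
        format_fraction(cl$tract$modal_k,
                        round(cl$tract$modal_k / cl$tract$modal_freq)),
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        format_fraction(cl$carriers, cl$total))
  }
  add("-- stop-loss concordance --")
  if (length(run$concordance) == 0) add("  none") else
    for (cc in run$concordance) {
      add("  %s:%d (%s, %s): concordance %.3f, variant freq %.4f, inversion freq %.4f",
          cc$site$scaffold, cc$site$pos, cc$site$gene_id, cc$population,
          cc$concordance, cc$variant_frequency, cc$inversion_frequency)
    }
  add("-- population summary statistics (autosomes) --")
  for (pn in names(run$popstats)) {
    p <- run$popstats[[pn]]
    add("  %s: pi0=%.5f pi4=%.5f D0=%.3f D4=%.3f pN=%s pS=%s pN/pS=%s",
        pn, p$pi0, p$pi4, p$D0, p$D4,
        format(p$pN, digits = 3), format(p$pS, digits = 3),
        format(p$pNpS, digits = 3))
  }
  add("-- expression enrichment in outlier regions --")
  if (length(run$expression$enrichment) == 0) add("  none") else
    for (nm in names(run$expression$enrichment)) {
      e <- run$expression$enrichment[[nm]]
      if (!is.null(e$error)) add("  %s: %s", nm, e$error)
      else add("  %s: X2=%.3f df=%d p=%.4f", nm, e$statistic, e$df, e$p_value)
    }

  summary <- list(
    genome_wide_fst = run$fst$genome_wide,
    outlier_regions = lapply(run$fst$outliers, function(o)
      o[, c("scaffold", "start", "end", "peak_fst")]),
    inversions = lapply(run$calls, function(cl)
      list(population = cl$tract$population, scaffold = cl$tract$scaffold,
           start = cl$tract$start, end = cl$tract$end,
           modal_frequency = cl$tract$modal_freq,
           carriers = cl$carriers, total = cl$total,
           frequency = cl$frequency,
           fraction = format_fraction(cl$carriers, cl$total))),
    concordance = run$concordance,
    popstats = run$popstats,
    polarization_counts = run$ancestral_counts)
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(text = L, summary = summary)
}

#' @export
print.hs_run <- function(x, ...) {
  cat(report_render(x)$text, sep = "\n")
  invisible(x)
}
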