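#' Build the study's exposure-outcome pair plan
#'
#' Primary pairs are every (earlier, later) combination under the transitive
#' closure of the temporal partial order. Declared bidirectional pairs
#' contribute both directions. The ovarian-reserve reverse analyses add
#' menopause as an exposure for the earlier factors, and the five fixed
#' negative-control pairs run the clock backwards (outcome precedes
#' exposure), where any signal indicates shared pleiotropy. A duplicate
#' ordered pair keeps its highest-priority category (negative control >
#' primary > reverse > bidirectional).
#'
#' @param registry Trait registry tibble (default [trait_registry()]).
#' @param temporal_order Tibble `earlier, later` (default
#'   [default_temporal_order()]); must be acyclic.
#' @param bidirectional_pairs Tibble `a, b`, each yielding two plan rows.
#'   Default: number of births, parous status and partners against every
#'   trait they are not ordered against.
#' @return A `pair_plan` tibble: `exposure, outcome, category`.
#' @export
build_pair_plan <- function(registry = trait_registry(),
                            temporal_order = default_temporal_order(),
                            bidirectional_pairs = NULL) {
  ids <- registry$trait
  edges <- as_tibble(temporal_order) |>
    filter(.data$earlier %in% ids, .data$later %in% ids)
  topological_order(ids, tibble(from = edges$earlier, to = edges$later,
                                theta = 1))  # cycle check
  # transitive closure by boolean matrix powers
  p <- length(ids)
  A <- matrix(FALSE, p, p, dimnames = list(ids, ids))
  if (nrow(edges)) A[cbind(edges$earlier, edges$later)] <- TRUE
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  closure <- which(A, arr.ind = TRUE)
  primary <- tibble(exposure = ids[closure[, 1]], outcome = ids[closure[, 2]],
                    category = "primary")

  if (is.null(bidirectional_pairs)) {
    free <- c("n_births", "parous", "partners")
    bidirectional_pairs <- purrr::map_dfr(intersect(free, ids), function(t) {
      others <- setdiff(ids, t)
      unordered <- others[!A[t, others] & !A[others, t]]
      if (length(unordered)) tibble(a = t, b = unordered) else NULL
    }) |> distinct()
  }
  bidir <- NULL
  if (!is.null(bidirectional_pairs) && nrow(as_tibble(bidirectional_pairs))) {
    bp <- as_tibble(bidirectional_pairs)
    bidir <- tibble(exposure = c(bp$a, bp$b), outcome = c(bp$b, bp$a),
                    category = "bidirectional")
  }

  reverse <- tibble(exposure = "menopause",
                    outcome = intersect(c("menarche", "afs", "afb"), ids),
                    category = "reverse_menopause")
  negctl <- tibble(
    exposure = c("afb", "afs", "afb", "menopause", "alb"),
    outcome  = c("menarche", "menarche", "afs", "afs", "menarche"),
    category = "negative_control")

  plan <- bind_rows(negctl, primary, reverse, bidir) |>
    filter(.data$exposure %in% ids, .data$outcome %in% ids) |>
    distinct(.data$exposure, .data$outcome, .keep_all = TRUE) |>
    arrange(match(.data$category,
                  c("primary", "bidirectional", "reverse_menopause",
                    "negative_control")),
            match(.data$exposure, ids), match(.data$outcome, ids))
  structure(plan, class = c("pair_plan", class(plan)))
}

#' Run the full MR suite for one exposure-outcome pair
#'
#' Harmonises the instrument subset of the exposure statistics with the
#' outcome statistics and runs: IVW with Cochran's Q and the mean F
#' statistic; the Steiger directionality test; with k >= 3 also MR-Egger
#' (plus its I2_GX, and SIMEX when I2_GX < `simex_threshold`), weighted
#' median and weighted mode; with k >= 4 also MR-PRESSO. Pairs without
#' instruments are returned with a skipped status rather than an error.
#'
#' @param exposure_stats,outcome_stats [sumstats()] tibbles.
#' @param instruments An `instrument_set` or character vector of SNP ids.
#' @param n_boot Bootstrap replicates for median/mode SEs.
#' @param n_sim MR-PRESSO null simulations.
#' @param simex_threshold Run SIMEX when I2_GX falls below this (default
#'   0.9).
#' @param seed Integer seed governing every stochastic component.
#' @return A list: `results` (tidy tibble, one row per method), `status`,
#'   `harmonised`, `diagnostics` (Q, F, Steiger, PRESSO, I2_GX, seeds).
#' @export
run_pair <- function(exposure_stats, outcome_stats, instruments,
                     n_boot = 1000, n_sim = 1000, simex_threshold = 0.9,
                     seed = 1L) {
  snps <- if (inherits(instruments, "instrument_set")) instruments$snp
          else instruments
  empty <- list(results = tibble(), status = "no_instruments",
                harmonised = NULL, diagnostics = NULL)
  if (length(snps) == 0) return(empty)
  es <- exposure_stats[exposure_stats$snp %in% snps, ]
  h <- tryCatch(harmonise(es, outcome_stats), error = function(e) NULL)
  if (is.null(h) || nrow(h) == 0) {
    empty$status <- "empty_harmonised"
    return(empty)
  }
  k <- nrow(h)
  n_exp <- median(exposure_stats$n)
  n_out <- median(outcome_stats$n)

  res <- list(mr_ivw(h))
  diagnostics <- list(seed = seed, k = k)
  if (k >= 2) diagnostics$Q <- cochran_q(h, res[[1]]$estimate)
  if (inherits(instruments, "instrument_set") &&
      nrow(instruments) > 0 && attr(instruments, "r2_total") < 1) {
    diagnostics$r2_total <- attr(instruments, "r2_total")
    diagnostics$mean_f <- mean_f_statistic(attr(instruments, "r2_total"),
                                           n_exp, length(snps))
  }
  diagnostics$steiger <- steiger(h, n_exp, n_out)
  if (k >= 3) {
    egger <- mr_egger(h)
    res <- c(res, list(egger,
                       weighted_median(h, n_boot, child_seed(seed, "median")),
                       weighted_mode(h, n_boot = n_boot,
                                     seed = child_seed(seed, "mode"))))
    diagnostics$i2_gx <- egger$i2_gx
    if (!egger$skipped && egger$i2_gx < simex_threshold) {
      res <- c(res, list(simex_egger(h, seed = child_seed(seed, "simex"))))
    }
  } else {
    res <- c(res, list(skipped_result("egger", h, "needs k >= 3"),
                       skipped_result("weighted_median", h, "needs k >= 3"),
                       skipped_result("weighted_mode", h, "needs k >= 3")))
  }
  if (k >= 4) {
    diagnostics$presso <- mr_presso(h, n_sim = n_sim,
                                    seed = child_seed(seed, "presso"))
    if (!is.null(diagnostics$presso$corrected)) {
      res <- c(res, list(diagnostics$presso$corrected))
    }
  }
  list(results = purrr::map_dfr(res, tidy), status = "ok", harmonised = h,
       diagnostics = diagnostics)
}

#' Fixed-effects meta-analysis of two MR results
#'
#' Inverse-variance pooling: `est = sum(est_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`, with a between-estimate Cochran Q on 1
#' degree of freedom.
#'
#' @param result_a,result_b `mr_result` objects for the same
#'   exposure/outcome/method.
#' @return A `meta_result` list: `estimate, se, ci_lower, ci_upper, p,
#'   per_half` (tibble), `Q, Q_p, method`.
#' @export
meta_fixed <- function(result_a, result_b) {
  same <- identical(result_a$method, result_b$method) &&
    identical(result_a$exposure, result_b$exposure) &&
    identical(result_a$outcome, result_b$outcome)
  if (!same) abort("meta_fixed requires matching exposure/outcome/method")
  est <- c(result_a$estimate, result_b$estimate)
  se <- c(result_a$se, result_b$se)
  w <- 1 / se^2
  pooled <- sum(w * est) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  Q <- sum(w * (est - pooled)^2)
  structure(
    list(estimate = pooled, se = pooled_se,
         ci_lower = pooled - ci_mult * pooled_se,
         ci_upper = pooled + ci_mult * pooled_se,
         p = p_from_z(pooled / pooled_se),
         per_half = tibble(half = c("a", "b"), estimate = est, se = se),
         Q = Q, Q_df = 1L, Q_p = pchisq(Q, 1, lower.tail = FALSE),
         method = result_a$method, exposure = result_a$exposure,
         outcome = result_a$outcome),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %s: pooled b = %.4f (SE %.4f), between-half Q p = %.3g\n",
              x$method, x$estimate, x$se, x$Q_p))
  invisible(x)
}

#' Split-sample MR study
#'
#' Divides the cohort into random halves, runs the GWAS per half, and for
#' each plan pair performs MR twice — exposure from one half against outcome
#' from the other, and vice versa — pooling the IVW estimates with
#' [meta_fixed()]. When only one half yields instruments for an exposure the
#' pair is run once (no pooling); with none it is skipped with a status. LD
#' for clumping always comes from the shared full reference panel.
#'
#' @param panel A `genotype_panel`.
#' @param traits The matching `trait_table`.
#' @param plan A `pair_plan` (default built from the trait attributes).
#' @param seed Integer seed (drives the split and downstream draws).
#' @param p_threshold,clump_r2,clump_kb Instrument-selection parameters.
#' @return A tibble with one row per (pair, direction) plus pooled rows
#'   (`direction = "pooled"`); columns `exposure, outcome, category,
#'   direction, nsnp, b, se, lo_ci, up_ci, p, q_between, q_between_p,
#'   status`.
#' @export
run_split_sample_study <- function(panel, traits, plan = NULL, seed = 1L,
                                   p_threshold = 5e-8, clump_r2 = 0.001,
                                   clump_kb = 10000) {
  config <- attr(traits, "config")
  plan <- plan %||% build_pair_plan(config$traits)
  halves <- split_cohort(panel, traits, seed = child_seed(seed, "split"))
  needed <- unique(c(plan$exposure, plan$outcome))
  types <- attr(traits, "types")

  gwas_half <- function(half) {
    stats <- lapply(needed, function(t) {
      s <- run_gwas(half$panel, half$traits, t)
      if (types[[t]] == "continuous") standardise_sumstats(s) else s
    })
    names(stats) <- needed
    stats
  }
  stats_a <- gwas_half(halves$a)
  stats_b <- gwas_half(halves$b)
  instr_a <- lapply(stats_a, select_instruments, ld_source = panel,
                    p_threshold = p_threshold, clump_r2 = clump_r2,
                    clump_kb = clump_kb)
  instr_b <- lapply(stats_b, select_instruments, ld_source = panel,
                    p_threshold = p_threshold, clump_r2 = clump_r2,
                    clump_kb = clump_kb)

  one_direction <- function(exp_stats, out_stats, instr) {
    if (nrow(instr) == 0) return(NULL)
    h <- harmonise(exp_stats[exp_stats$snp %in% instr$snp, ], out_stats)
    if (nrow(h) == 0) return(NULL)
    res <- mr_ivw(h)
    res$exposure <- attr(exp_stats, "trait_id")
    res$outcome <- attr(out_stats, "trait_id")
    res
  }

  rows <- purrr::pmap_dfr(plan, function(exposure, outcome, category) {
    r_ab <- one_direction(stats_a[[exposure]], stats_b[[outcome]],
                          instr_a[[exposure]])
    r_ba <- one_direction(stats_b[[exposure]], stats_a[[outcome]],
                          instr_b[[exposure]])
    row_of <- function(r, direction) {
      tibble(exposure = exposure, outcome = outcome, category = category,
             direction = direction, nsnp = r$k, b = r$estimate, se = r$se,
             lo_ci = r$ci_lower, up_ci = r$ci_upper, p = r$p,
             q_between = NA_real_, q_between_p = NA_real_, status = "ok")
    }
    out <- tibble()
    if (!is.null(r_ab)) out <- bind_rows(out, row_of(r_ab, "a_on_b"))
    if (!is.null(r_ba)) out <- bind_rows(out, row_of(r_ba, "b_on_a"))
    if (!is.null(r_ab) && !is.null(r_ba)) {
      # pool only the common label; halves are disjoint so fixed effects apply
      r_ba2 <- r_ba
      r_ba2$exposure <- r_ab$exposure
      r_ba2$outcome <- r_ab$outcome
      mt <- meta_fixed(r_ab, r_ba2)
      out <- bind_rows(out, tibble(
        exposure = exposure, outcome = outcome, category = category,
        direction = "pooled", nsnp = r_ab$k + r_ba$k, b = mt$estimate,
        se = mt$se, lo_ci = mt$ci_lower, up_ci = mt$ci_upper, p = mt$p,
        q_between = mt$Q, q_between_p = mt$Q_p, status = "ok"))
    }
    if (nrow(out) == 0) {
      out <- tibble(exposure = exposure, outcome = outcome,
                    category = category, direction = "none",
                    nsnp = 0L, b = NA_real_, se = NA_real_, lo_ci = NA_real_,
                    up_ci = NA_real_, p = NA_real_, q_between = NA_real_,
                    q_between_p = NA_real_, status = "no_instruments")
    }
    out
  })
  rows
}

#' Run the full synthetic study end to end
#'
#' Simulates a cohort from the causal configuration, runs the per-trait GWAS
#' (continuous traits SD-standardised), computes LD scores and the pairwise
#' genetic-correlation matrix, selects instruments, executes the pair plan
#' with the full sensitivity suite (negative controls included as plan
#' categories), and runs the split-sample meta-analysis. Per-pair failures
#' are caught and reported as status rows, never fatal to the bundle.
#'
#' @param config A [causal_config()].
#' @param n Cohort size (default 20000).
#' @param blocks Panel layout (default: enough 10-SNP blocks at rho 0.5 for
#'   twice the configured causal SNPs, spread over chromosomes 1-22 with a
#'   share on chromosome 6 so the MHC exclusion is exercised).
#' @param seed Integer seed for the whole study.
#' @param out_dir Optional directory; when given, every table is written as
#'   TSV together with a run manifest.
#' @param plan Optional `pair_plan`; defaults to [build_pair_plan()] on the
#'   config's trait registry.
#' @param n_boot,n_sim See [run_pair()].
#' @param ld_window_kb LD-score window.
#' @param split_sample Run the split-sample stage (default TRUE).
#' @return A `study_report` list: `rg_matrix` (tibble), `mr_results`,
#'   `sensitivity` (heterogeneity / egger intercepts / presso / steiger
#'   tibbles), `split_meta`, `instruments` (per-trait counts, r2, F),
#'   `manifest`.
#' @export
run_full_study <- function(config = causal_config(), n = 20000, blocks = NULL,
                           seed = 1L, out_dir = NULL, plan = NULL,
                           n_boot = 500, n_sim = 1000, ld_window_kb = 1000,
                           split_sample = TRUE) {
  total_causal <- sum(config$n_snps_per_trait)
  blocks <- blocks %||% genotype_blocks(
    n_blocks = ceiling(total_causal * 2 / 10), snps_per_block = 10,
    rho = 0.5, chr = rep(c(1:5, 6L, 7:22), length.out =
                           ceiling(total_causal * 2 / 10)))
  panel <- simulate_genotypes(n, blocks, seed = child_seed(seed, "panel"))
  config$seed <- child_seed(seed, "config")
  traits <- simulate_traits(panel, config)
  types <- attr(traits, "types")
  ids <- config$traits$trait

  stats <- lapply(ids, function(t) {
    s <- run_gwas(panel, traits, t)
    if (types[[t]] == "continuous") standardise_sumstats(s) else s
  })
  names(stats) <- ids

  ld <- compute_ld_scores(panel, window_kb = ld_window_kb)
  ztabs <- lapply(stats, function(s) {
    tryCatch(munge(s, ld), error = function(e) NULL)
  })
  rg_rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      res <- tryCatch({
        r <- ldsc_rg(ztabs[[i]], ztabs[[j]], ld)
        tibble(trait1 = ids[i], trait2 = ids[j], rg = r$rg, se = r$rg_se,
               p = r$rg_p, h2_1 = r$h2$trait1[["est"]],
               h2_2 = r$h2$trait2[["est"]],
               bivariate_intercept = r$intercepts$bivariate[["est"]],
               status = "ok")
      }, error = function(e) {
        tibble(trait1 = ids[i], trait2 = ids[j], rg = NA_real_, se = NA_real_,
               p = NA_real_, h2_1 = NA_real_, h2_2 = NA_real_,
               bivariate_intercept = NA_real_, status = conditionMessage(e))
      })
      rg_rows[[length(rg_rows) + 1]] <- res
    }
  }
  rg_matrix <- bind_rows(rg_rows)

  instr <- lapply(stats, select_instruments, ld_source = panel)
  instrument_tbl <- purrr::map_dfr(ids, function(t) {
    it <- instr[[t]]
    n_exp <- median(stats[[t]]$n)
    tibble(trait = t, nsnp = nrow(it), r2_total = attr(it, "r2_total"),
           mean_f = if (nrow(it) > 0)
             mean_f_statistic(attr(it, "r2_total"), n_exp, nrow(it))
           else NA_real_)
  })

  plan <- plan %||% build_pair_plan(config$traits)
  pair_out <- purrr::pmap(plan[, c("exposure", "outcome", "category")],
                          function(exposure, outcome, category) {
    tryCatch(
      run_pair(stats[[exposure]], stats[[outcome]], instr[[exposure]],
               n_boot = n_boot, n_sim = n_sim,
               seed = child_seed(seed, paste0(exposure, "_", outcome))),
      error = function(e) list(results = tibble(), status = conditionMessage(e),
                               harmonised = NULL, diagnostics = NULL))
  })
  mr_results <- purrr::map2_dfr(pair_out, seq_len(nrow(plan)), function(po, i) {
    if (nrow(po$results) == 0) {
      return(tibble(exposure = plan$exposure[i], outcome = plan$outcome[i],
                    category = plan$category[i], method = NA_character_,
                    nsnp = 0L, b = NA_real_, se = NA_real_, lo_ci = NA_real_,
                    up_ci = NA_real_, p = NA_real_, status = po$status))
    }
    mutate(po$results, category = plan$category[i], status = po$status)
  })

  sensitivity <- list(
    heterogeneity = purrr::map2_dfr(pair_out, seq_len(nrow(plan)), function(po, i) {
      q <- po$diagnostics$Q
      if (is.null(q)) return(tibble())
      tibble(exposure = plan$exposure[i], outcome = plan$outcome[i],
             Q = q$Q, df = q$df, p = q$p, heterogeneity = q$heterogeneity)
    }),
    egger_intercept = filter(mr_results, .data$method %in% "egger"),
    steiger = purrr::map2_dfr(pair_out, seq_len(nrow(plan)), function(po, i) {
      st <- po$diagnostics$steiger
      if (is.null(st)) return(tibble())
      tibble(exposure = plan$exposure[i], outcome = plan$outcome[i],
             r2_exposure = st$r2_exposure, r2_outcome = st$r2_outcome,
             direction_correct = st$direction_correct, p = st$p)
    }),
    presso = purrr::map2_dfr(pair_out, seq_len(nrow(plan)), function(po, i) {
      pr <- po$diagnostics$presso
      if (is.null(pr)) return(tibble())
      tibble(exposure = plan$exposure[i], outcome = plan$outcome[i],
             global_p = pr$global_p, n_outliers = length(pr$outliers),
             distortion_p = pr$distortion_p)
    })
  )

  split_meta <- NULL
  if (split_sample) {
    split_meta <- run_split_sample_study(panel, traits, plan,
                                         seed = child_seed(seed, "splitstudy"))
  }

  manifest <- list(
    seed = seed, n = n, n_snps = ncol(panel$dosages),
    traits = ids, p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
    ld_window_kb = ld_window_kb, n_boot = n_boot, n_sim = n_sim,
    package_version = as.character(utils::packageVersion("mrfactors")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  report <- structure(
    list(rg_matrix = rg_matrix, mr_results = mr_results,
         sensitivity = sensitivity, split_meta = split_meta,
         instruments = instrument_tbl, plan = plan, manifest = manifest),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  pairs:", nrow(x$plan), "| MR rows:", nrow(x$mr_results),
      "| rg pairs:", nrow(x$rg_matrix), "\n")
  invisible(x)
}

#' Write a study report bundle as TSV files plus a manifest
#'
#' @param report A `study_report` from [run_full_study()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) if (!is.null(x) && nrow(as_tibble(x)) >= 0) {
    readr::write_tsv(as_tibble(x), file.path(out_dir, name))
  }
  w(report$rg_matrix, "genetic_correlations.tsv")
  w(report$mr_results, "mr_results.tsv")
  w(report$sensitivity$heterogeneity, "heterogeneity.tsv")
  w(report$sensitivity$egger_intercept, "egger_intercepts.tsv")
  w(report$sensitivity$steiger, "steiger.tsv")
  w(report$sensitivity$presso, "presso.tsv")
  w(report$split_meta, "split_sample_meta.tsv")
  w(report$instruments, "instruments.tsv")
  w(report$plan, "pair_plan.tsv")
  writeLines(jsonlite_manifest(report$manifest), file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

# minimal JSON writer for the manifest (flat list of scalars/vectors),
# avoiding a hard jsonlite dependency
jsonlite_manifest <- function(x) {
  enc <- function(v) {
    if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15)
  }
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (length(v) == 1) enc(v) else
      paste0("[", paste(enc(v), collapse = ", "), "]")
    sprintf('  "%s": %s', nm, val)
  }, character(1))
  c("{", paste(items, collapse = ",\n"), "}")
}
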