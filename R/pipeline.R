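#' Generate the synthetic venom-expression demo dataset
#'
#' Writes a reproducible stand-in for a comparative venom-transcriptome
#' compilation: a 52-tip ultrametric tree of depth 60 My with three clades
#' (emulating the three venomous snake families), and a 52-species x
#' 10-toxin relative-abundance table (rows summing to 1, a subset of
#' species with replicate transcriptomes) in which each toxin's underlying
#' trait evolved under a stated model — including at least one
#' rate-shifted-BM toxin with a known shift for end-to-end shift-recovery
#' checks, and one sparse toxin for presence-filter checks. All values are
#' synthetic; the generating model and parameters for every toxin are
#' recorded in the manifest.
#'
#' @param seed Integer seed; the same seed gives byte-identical files.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the tree, the expression table, the
#'   per-toxin generating specs and the file paths.
#' @export
make_demo_data <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_by_clade <- c(Colubridae = 10L, Viperidae = 22L, Elapidae = 20L)
  depth <- 60
  with_seed(seed, {
    # three clades on a fixed backbone: root at 60 My, viperid-elapid
    # split at 45 My, crown families at 40 (colubrids) / 35 My
    sub <- list(
      Colubridae = simulate_pure_birth_tree(n_by_clade[1], 40),
      Viperidae = simulate_pure_birth_tree(n_by_clade[2], 35),
      Elapidae = simulate_pure_birth_tree(n_by_clade[3], 35))
    for (fam in names(sub)) {
      sub[[fam]]$tip.label <- sprintf("%s_sp%02d", fam,
                                      seq_len(ape::Ntip(sub[[fam]])))
    }
    newick_of <- function(tr) sub(";$", "", ape::write.tree(tr))
    nwk <- sprintf("(%s:20,(%s:10,%s:10):15);",
                   newick_of(sub$Colubridae), newick_of(sub$Viperidae),
                   newick_of(sub$Elapidae))
    tree <- validate_timetree(ape::read.tree(text = nwk))

    # generating model per toxin; rates in trait^2 / My on the scaled axis
    toxin_specs <- list(
      BPP   = levy_model_spec("JN", lambda = 0.08, delta = 2,
                              sigma_tip = 0.2),
      CRISP = levy_model_spec("NIG", alpha_nig = 1, delta_nig = 0.3,
                              sigma_tip = 0.2),
      CTL   = levy_model_spec("JN", lambda = 0.05, delta = 3,
                              sigma_tip = 0.2),
      GF    = levy_model_spec("BMJN", sigma2 = 0.05, lambda = 0.08,
                              delta = 2, sigma_tip = 0.2),
      KSPI  = levy_model_spec("NIG", alpha_nig = 0.5, delta_nig = 0.25,
                              sigma_tip = 0.2),
      LAAO  = levy_model_spec("BM", sigma2 = 0.3, sigma_tip = 0.2),
      SVMP  = "SHIFTED_BM",
      SVSP  = levy_model_spec("OU", sigma2 = 0.5, alpha = 0.05,
                              sigma_tip = 0.2),
      TFTx  = levy_model_spec("EB", sigma2 = 1.5, r = -0.05,
                              sigma_tip = 0.2),
      vPLA2 = levy_model_spec("JN", lambda = 0.1, delta = 1.8,
                              sigma_tip = 0.2))

    # the SVMP shift: a rate increase on the viperid stem branch
    vip_mrca <- ape::getMRCA(tree, tree$tip.label[grepl("Viperidae",
                                                        tree$tip.label)])
    vip_stem <- which(tree$edge[, 2] == vip_mrca)
    h <- node_heights(tree)
    svmp_shift <- shift_configuration(
      tibble::tibble(edge = vip_stem,
                     time = h[tree$edge[vip_stem, 1]] +
                       0.5 * tree$edge.length[vip_stem],
                     beta = 1.5, b = 0),
      root_beta = 0.15, root_b = 0)

    traits <- purrr::imap(toxin_specs, function(spec, nm) {
      if (identical(spec, "SHIFTED_BM")) {
        simulate_shifted_bm(tree, svmp_shift, sigma_tip = 0.2)
      } else {
        simulate_levy_traits(tree, spec)
      }
    })

    # map traits to a relative composition: exp(baseline + clade offset +
    # trait z-score), normalised per species
    z <- vapply(traits, function(tr) scale(tr$value)[, 1], numeric(52))
    rownames(z) <- tree$tip.label
    baseline <- stats::setNames(
      c(-1, -0.5, -1.5, -2, -2, -1, 1, 0.5, 0.5, 0), names(toxin_specs))
    clade_of <- sub("_sp.*$", "", tree$tip.label)
    offs <- matrix(0, 3, 10, dimnames = list(names(n_by_clade),
                                             names(toxin_specs)))
    offs["Viperidae", c("SVMP", "vPLA2", "SVSP", "BPP")] <- c(1, 1, .5, .5)
    offs["Elapidae", c("TFTx", "CTL")] <- c(2, 0.5)
    offs["Colubridae", c("CRISP", "GF")] <- c(1, 0.5)
    raw <- exp(sweep(z, 2, baseline, "+") + offs[clade_of, ])

    # one sparse toxin: KSPI absent from a fixed 40% of species
    absent <- sort(sample(seq_len(52), 21))
    raw[absent, "KSPI"] <- 0
    comp <- raw / rowSums(raw)

    # replicicate transcriptomes for 10 species: relative abundances
    # re-measured with multiplicative noise
    rep_sp <- sort(sample(tree$tip.label, 10))
    rep_rows <- comp[rep_sp, , drop = FALSE] *
      matrix(stats::rlnorm(length(rep_sp) * 10, 0, 0.15),
             length(rep_sp), 10)
    rep_rows <- rep_rows / rowSums(rep_rows)
    tbl <- tibble::as_tibble(rbind(comp, rep_rows), rownames = "species")
    tbl <- tbl[order(tbl$species), ]

    tree_path <- file.path(dir, "tree.nwk")
    expr_path <- file.path(dir, "expression.tsv")
    manifest_path <- file.path(dir, "manifest.json")
    ape::write.tree(tree, tree_path)
    readr::write_tsv(tbl, expr_path)
    manifest <- list(
      seed = seed, depth_my = depth, n_species = 52,
      clades = as.list(n_by_clade),
      replicated_species = rep_sp,
      sparse_toxin = "KSPI",
      generating_models = purrr::imap(toxin_specs, function(s, nm) {
        if (identical(s, "SHIFTED_BM")) {
          list(model = "SHIFTED_BM", root_beta = svmp_shift$root_beta,
               shift_edge = svmp_shift$events$edge,
               shift_beta = svmp_shift$events$beta)
        } else {
          s[.levy_model_params[[s$model]]]
        }
      }))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(tree = tree, expression = tbl, specs = toxin_specs,
                   shift = svmp_shift,
                   paths = list(tree = tree_path, expression = expr_path,
                                manifest = manifest_path)))
  })
}

write_tsv_with_header <- function(tbl, path, header_lines) {
  hdr <- paste0("# ", header_lines, collapse = "\n")
  writeLines(paste0(hdr, "\n", readr::format_tsv(tbl)), path, sep = "")
  invisible(path)
}

run_stage <- function(out_dir, stage, code) {
  t0 <- Sys.time()
  res <- tryCatch(force(code), error = function(e) {
    writeLines(paste0("FAILED at stage '", stage, "': ",
                      conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  list(result = res,
       seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full toxin-evolution analysis
#'
#' End-to-end pipeline: load tree and expression table, apply the presence
#' filter, and for each retained toxin scale by the average within-species
#' variance, prune to the shared species, fit all requested trait-evolution
#' models with Akaike-weight comparison and the two-fold selection rule,
#' and (optionally) run the rate-shift rjMCMC with Bayes factor, best shift
#' configuration, per-branch rates and rate-through-time curves. All
#' outputs are TSV/JSON under `out_dir`, with a manifest recording
#' settings, seeds and per-stage runtimes; rerunning with the same inputs
#' and seed reproduces every output.
#'
#' @param tree_file Newick tree path.
#' @param expression_file Expression table path.
#' @param out_dir Output directory (created if needed).
#' @param presence_threshold Presence-filter fraction (default 0.5).
#' @param models Models to fit (default all nine).
#' @param restarts,grid_size Passed to [fit_model()].
#' @param mcmc_generations,mcmc_thin,expected_shifts Passed to
#'   [rjmcmc_run()].
#' @param clades Optional named list of tip-label vectors; each gets its
#'   own rate-through-time table per toxin.
#' @param seed Integer seed governing all stochastic stages.
#' @param do_model_fit,do_rate_shifts Stage toggles.
#' @return Invisibly, a list with the comparison table and per-toxin
#'   results.
#' @export
run_full_analysis <- function(tree_file, expression_file, out_dir,
                              presence_threshold = 0.5,
                              models = levy_models(), restarts = 10,
                              grid_size = 1024, mcmc_generations = 2e6,
                              mcmc_thin = 200, expected_shifts = 1,
                              clades = NULL, seed = 1,
                              do_model_fit = TRUE, do_rate_shifts = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  runtimes <- list()

  st <- run_stage(out_dir, "load", {
    list(tree = read_newick(tree_file),
         expr = read_expression_table(expression_file))
  })
  runtimes$load <- st$seconds
  tree <- st$result$tree
  expr <- st$result$expr

  st <- run_stage(out_dir, "presence_filter", {
    presence_filter(expr, min_fraction = presence_threshold)
  })
  runtimes$presence_filter <- st$seconds
  expr <- st$result
  toxins <- setdiff(names(expr), "species")

  comparison_rows <- list()
  fits_json <- list()
  shift_rows <- list()
  per_toxin <- list()

  for (ti in seq_along(toxins)) {
    tx <- toxins[ti]
    st <- run_stage(out_dir, paste0("scale:", tx), {
      tr <- scale_by_within_species_variance(expr, tx)
      prune_to_overlap(tree, tr)
    })
    runtimes[[paste0("scale:", tx)]] <- st$seconds
    ptree <- st$result$tree
    ptrait <- st$result$trait
    write_scaled_trait(ptrait, file.path(out_dir,
                                         paste0("trait_", tx, ".tsv")))
    res_tx <- list(trait = ptrait)

    if (do_model_fit) {
      st <- run_stage(out_dir, paste0("model_fit:", tx), {
        compare_models(ptree, ptrait, models = models, restarts = restarts,
                       grid_size = grid_size, seed = seed + 1000 * ti)
      })
      runtimes[[paste0("model_fit:", tx)]] <- st$seconds
      cmp <- st$result
      cw <- stats::setNames(cmp$classes$weight, cmp$classes$class)
      comparison_rows[[tx]] <- tibble::tibble(
        toxin = tx,
        BM = unname(cw["BM"]), OU = unname(cw["OU"]), EB = unname(cw["EB"]),
        pulsed = unname(cw["pulsed"]),
        selected = select_best(cmp))
      fits_json[[tx]] <- purrr::map(attr(cmp, "fits"), function(f) {
        list(params = f$params, loglik = f$loglik, k = f$k, AIC = f$aic,
             converged = f$converged)
      })
      res_tx$comparison <- cmp
    }

    if (do_rate_shifts) {
      st <- run_stage(out_dir, paste0("rate_shifts:", tx), {
        rjmcmc_run(ptree, ptrait, ngenerations = mcmc_generations,
                   thin = mcmc_thin, expected_shifts = expected_shifts,
                   seed = seed + 1000 * ti + 1)
      })
      runtimes[[paste0("rate_shifts:", tx)]] <- st$seconds
      ms <- st$result
      bf <- compute_bayes_factor(ms)
      best <- best_shift_configuration(ms)
      br <- branch_rates(ms)
      shift_rows[[tx]] <- tibble::tibble(
        toxin = tx, bayes_factor = bf$bf, bf_is_lower_bound = bf$is_bound,
        posterior_p0 = bf$posterior_p0, n_core_shifts = nrow(best$events),
        ess_loglik = as.numeric(ess(ms$samples$loglik)),
        ess_nshifts = as.numeric(ess(ms$samples$nshifts)))
      write_tsv_with_header(
        br, file.path(out_dir, paste0("branch_rates_", tx, ".tsv")),
        c(paste0("per-branch posterior mean rate, toxin ", tx),
          "mean_rate in trait^2 per My; edge indexes tree$edge rows"))
      annotated_newick(ptree, br,
                       file.path(out_dir,
                                 paste0("branch_rates_", tx, ".nwk")))
      rtt_targets <- c(list(all = NULL), clades %||% list())
      for (cl in names(rtt_targets)) {
        rtt <- rate_through_time(ms, clade = rtt_targets[[cl]])
        write_tsv_with_header(
          rtt, file.path(out_dir,
                         paste0("rtt_", tx, "_", cl, ".tsv")),
          c(paste0("rate through time, toxin ", tx, ", clade ", cl),
            "time_before_present in My; rates in trait^2 per My;",
            "band is the central 90% posterior interval"))
      }
      if (nrow(best$events) > 0) {
        write_tsv_with_header(
          best$events,
          file.path(out_dir, paste0("best_shifts_", tx, ".tsv")),
          c(paste0("best (MAP) shift configuration, toxin ", tx),
            "time is absolute My from the root; beta in trait^2 per My"))
      }
      res_tx$shifts <- ms
      res_tx$bayes_factor <- bf
      res_tx$best_configuration <- best
    }
    per_toxin[[tx]] <- res_tx
  }

  comparison <- if (length(comparison_rows) > 0) {
    dplyr::bind_rows(comparison_rows)
  } else {
    NULL
  }
  if (!is.null(comparison)) {
    write_tsv_with_header(
      comparison, file.path(out_dir, "model_comparison.tsv"),
      c("Akaike weights per model class and selected class per toxin",
        "pulsed = maximum weight among the six jump models;",
        "selected by the two-fold Akaike-weight rule"))
    jsonlite::write_json(fits_json, file.path(out_dir, "model_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  shifts_summary <- if (length(shift_rows) > 0) {
    dplyr::bind_rows(shift_rows)
  } else {
    NULL
  }
  if (!is.null(shifts_summary)) {
    write_tsv_with_header(
      shifts_summary, file.path(out_dir, "shifts_summary.tsv"),
      c("rate-shift inference summary per toxin",
        "bayes_factor: posterior/prior odds of >=1 shift vs 0"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("levyshift")),
    r_version = R.version.string,
    inputs = list(tree = tree_file, expression = expression_file),
    settings = list(presence_threshold = presence_threshold,
                    models = models, restarts = restarts,
                    grid_size = grid_size,
                    mcmc_generations = mcmc_generations,
                    mcmc_thin = mcmc_thin,
                    expected_shifts = expected_shifts, seed = seed,
                    do_model_fit = do_model_fit,
                    do_rate_shifts = do_rate_shifts),
    toxins = toxins,
    runtimes_seconds = runtimes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(comparison = comparison, shifts_summary = shifts_summary,
                 per_toxin = per_toxin, manifest = manifest))
}
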