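#' Run the full sorted-population clonal-evolution pipeline
#'
#' Orchestrates filtering, CCF estimation, mutation clustering, clone-tree
#' construction, seeding inference, maximum parsimony, signature refitting,
#' and copy-number concordance for one patient, writing all result tables
#' to `outdir` plus a `report.json` summary and a `manifest.json` of output
#' file hashes. Deterministic given `seed`: rerunning with the same inputs
#' and seed reproduces every file byte for byte.
#'
#' @param input patient input bundle: a list with `variants` (long-format
#'   read-count table with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt_allele`, `gene`, `effect`, `context`, `patient`, `population`,
#'   `alt`, `depth`, `cn_t`), `purity_postsort` (named vector),
#'   `cn_profiles` (named list of segment tables), optional `facs` (named
#'   list of event tables per biopsy), and `site` (named vector
#'   `"primary"`/`"metastasis"`; taken from `config$populations` when the
#'   bundle comes from [simulate_patient()]).
#' @param outdir output directory (created if missing).
#' @param seed integer seed for the clustering restarts.
#' @param filter a [filter_config()].
#' @param pon_hits optional named panel-of-normals hit counts.
#' @param driver_genes character vector of driver genes; defaults to the
#'   packaged melanoma driver list.
#' @param signature_reference 96 x S signature matrix.
#' @param k_max maximum number of mutation clusters (default 8).
#' @param min_cluster_size minimum retained cluster size (default 5).
#' @param callable_mb callable megabases for TMB (default 35.7).
#' @param parsimony_mode trunk classification mode (`"strict"` or
#'   `"paper"`).
#' @param bin_size copy-number correlation bin size in bp (default 1 Mb).
#' @return invisibly, a list with the in-memory results of every stage
#'   (`populations`, `filtered`, `ccf`, `clusters`, `tree`, `seeding`,
#'   `parsimony`, `signatures`, `cnv`, `report`).
#' @export
run_pipeline <- function(input, outdir, seed = 1,
                         filter = filter_config(), pon_hits = NULL,
                         driver_genes = NULL,
                         signature_reference = toy_signature_reference(),
                         k_max = 8, min_cluster_size = 5, callable_mb = 35.7,
                         parsimony_mode = "strict", bin_size = 1e6) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(driver_genes)) {
    driver_genes <- read_driver_genes(
      system.file("extdata", "melanoma_driver_genes.txt", package = "clonesort"))
  }
  site <- input$site %||% stats::setNames(input$config$populations$site,
                                          input$config$populations$id)
  purity <- input$purity_postsort
  variants <- input$variants
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[clonesort] stage %-11s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  out <- list()

  out$populations <- stage("facs", {
    tab <- if (!is.null(input$facs)) {
      do.call(rbind, lapply(names(input$facs), function(b) {
        npop <- if (!is.null(input$config)) {
          sum(input$config$populations$biopsy == b)
        } else NULL
        g <- gate_populations(input$facs[[b]], n_populations = npop)
        cbind(biopsy = b, g)
      }))
    } else NULL
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(outdir, "populations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tab
  })

  out$filtered <- stage("filter", {
    fl <- apply_filters(variants, filter, pon_hits = pon_hits)
    write_variants_tsv(fl$retained, file.path(outdir, "filtered.maf.tsv"))
    jsonlite::write_json(as.list(fl$tally),
                         file.path(outdir, "filter_tally.json"),
                         auto_unbox = TRUE)
    fl
  })
  retained_ids <- unique(out$filtered$retained$variant_id)
  # full per-population counts (including zero-alt populations) for clustering
  full <- variants[variants$variant_id %in% retained_ids, , drop = FALSE]

  out$ccf <- stage("ccf", {
    ct <- ccf_table(full, purity)
    write_variants_tsv(
      ct[, c("variant_id", "population", "alt", "depth", "cn_t", "m",
             "ccf", "lo", "hi", "p_clonal", "clonality")],
      file.path(outdir, "ccf.tsv"))
    ct
  })

  out$clusters <- stage("clones", {
    if (length(retained_ids) == 0L) {
      warning("no variants survived filtering; skipping clustering")
      NULL
    } else {
      cl <- cluster_ccfs(out$ccf, purity, k_max = k_max, seed = seed)
      cl <- filter_clusters(cl, min_cluster_size)
      utils::write.table(ccf_trace(cl), file.path(outdir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cl
    }
  })

  out$cnv <- stage("cnv", {
    cats <- lapply(names(input$cn_profiles), function(p) {
      ploidy <- 2 * sum(with(input$cn_profiles[[p]],
                             (end - start) * total_cn)) /
        sum(with(input$cn_profiles[[p]], (end - start) * 2))
      cbind(population = p,
            call_cn_categories(input$cn_profiles[[p]], ploidy))
    })
    cats <- do.call(rbind, cats)
    utils::write.table(cats, file.path(outdir, "cnv_categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cors <- cn_correlation_matrix(input$cn_profiles, bin_size = bin_size)
    utils::write.table(round(cors$r, 6), file.path(outdir, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
    list(categories = cats, correlation = cors)
  })

  out$tree <- stage("clonetree", {
    if (is.null(out$clusters)) NULL else {
      tree <- build_clone_tree(out$clusters)
      jsonlite::write_json(
        list(root = tree$root, edges = tree$edges,
             ccf = as.data.frame(tree$ccf), unplaced = tree$unplaced),
        file.path(outdir, "clonetree.json"), auto_unbox = TRUE, digits = 6)
      writeLines(clone_tree_newick(tree), file.path(outdir, "clonetree.nwk"))
      tree
    }
  })

  out$seeding <- stage("seeding", {
    if (is.null(out$clusters) || !any(site == "metastasis")) NULL else {
      sd_res <- infer_seeding(out$clusters, site, out$cnv$correlation$r)
      jsonlite::write_json(sd_res, file.path(outdir, "seeding.json"),
                           auto_unbox = TRUE, digits = 6)
      sd_res
    }
  })

  out$parsimony <- stage("parsimony", {
    if (length(retained_ids) == 0L) NULL else {
      ret <- out$filtered$retained
      pres <- table(ret$variant_id, ret$population) > 0
      mat <- matrix(as.integer(pres), nrow(pres), ncol(pres),
                    dimnames = dimnames(pres))
      mp <- max_parsimony_tree(mat)
      ape::write.tree(mp$tree, file.path(outdir, "parsimony.nwk"))
      utils::write.table(mp$branch_counts,
                         file.path(outdir, "parsimony_branches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      mp$trunk_class <- classify_trunk(mat, parsimony_mode)
      mp
    }
  })

  out$signatures <- stage("signatures", {
    ret <- out$filtered$retained
    rows <- lapply(sort(unique(as.character(ret$population))), function(p) {
      ctx <- ret$context[ret$population == p & !is.na(ret$context)]
      if (length(ctx) == 0L) return(NULL)
      fit <- refit_signatures(context_spectrum(ctx), signature_reference)
      grouped <- group_others(fit$fractions)
      data.frame(population = p, signature = names(grouped),
                 fraction = as.numeric(grouped),
                 residual = fit$residual)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(outdir, "signatures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tab
  })

  out$report <- stage("report", {
    ret <- out$filtered$retained
    pops <- sort(unique(as.character(variants$population)))
    tmb_per_pop <- vapply(pops, function(p) {
      tmb(ret[ret$population == p, , drop = FALSE], callable_mb)
    }, numeric(1))
    shared <- if (length(pops) >= 2 && nrow(ret)) {
      sp <- shared_private_summary(ret, pops)
      list(shared_by_all_pct = sp["shared_by_all", "pct"],
           shared_by_some_pct = sp["shared_by_some", "pct"],
           private_pct = sp["private", "pct"])
    } else NULL
    drv <- driver_clonality_matrix(
      annotate_drivers(merge(ret, out$ccf[, c("variant_id", "population",
                                              "clonality")],
                             by = c("variant_id", "population")),
                       driver_genes))
    rep_obj <- list(
      seed = seed,
      n_input = nrow(variants), n_retained = nrow(ret),
      purity_postsort = as.list(purity),
      purity_summary = summarize_purity(unname(purity)),
      tmb_per_population = as.list(tmb_per_pop),
      shared_private = shared,
      driver = if (drv$n_driver > 0) {
        list(n_driver = drv$n_driver, n_clonal = drv$n_clonal,
             clonal_pct = drv$clonal_pct)
      } else list(n_driver = 0L),
      n_clusters = if (!is.null(out$clusters)) length(out$clusters$size) else 0,
      seeding = out$seeding,
      parsimony_score = if (!is.null(out$parsimony)) out$parsimony$score else NULL)
    jsonlite::write_json(rep_obj, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE,
                         null = "null")
    rep_obj
  })

  files <- sort(list.files(outdir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out)
}

#' One-command synthetic demonstration run
#'
#' Simulates the reference polygenomic patient ([patient1_config()]) and
#' runs the full pipeline on it.
#'
#' @param seed integer seed for both simulation and analysis.
#' @param outdir output directory.
#' @param ... passed to [run_pipeline()].
#' @return invisibly, list with `sim` (the simulation, including truth) and
#'   `result` (the pipeline outputs).
#' @export
run_demo <- function(seed = 17, outdir = tempfile("clonesort_demo"), ...) {
  sim <- simulate_patient(patient1_config(seed = seed))
  res <- run_pipeline(sim, outdir, seed = derive_seed(seed, 1), ...)
  invisible(list(sim = sim, result = res))
}
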