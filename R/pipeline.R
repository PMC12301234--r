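# End-to-end orchestration: simulate -> repertoire -> screen -> enrich ->
# triage -> aggregate (-> assays), with a manifest for provenance.

#' Simulate SPR-style binder labels from campaign ground truth
#'
#' Draws a class-balanced sample of clones (as an SPR follow-up panel would
#' be) and returns their binder labels with a configurable label-noise rate:
#' each label flips independently with probability \code{flip_rate},
#' emulating borderline-affinity miscalls.
#'
#' @param campaign Campaign with affinities assigned.
#' @param n_labels Total number of labelled clones (split evenly between
#'   classes where possible).
#' @param flip_rate Per-clone label flip probability.
#' @param seed Integer seed.
#' @return A tibble with \code{clone_id}, \code{aa}, \code{kd},
#'   \code{is_binder} (possibly flipped) and \code{true_binder}.
#' @export
simulate_spr_labels <- function(campaign, n_labels = 100, flip_rate = 0.05,
                                seed = 1) {
  cl <- campaign$clones
  stopifnot(!anyNA(cl$is_binder))
  with_seed(seed, {
    pos <- which(cl$is_binder)
    neg <- which(!cl$is_binder)
    n_pos <- min(length(pos), ceiling(n_labels / 2))
    n_neg <- min(length(neg), n_labels - n_pos)
    idx <- c(sample(pos, n_pos), sample(neg, n_neg))
    lab <- cl$is_binder[idx]
    flip <- stats::runif(length(idx)) < flip_rate
    tibble::tibble(clone_id = cl$clone_id[idx], aa = cl$aa[idx],
                   kd = cl$kd[idx], is_binder = xor(lab, flip),
                   true_binder = lab)
  })
}

#' Build a pipeline run configuration
#'
#' A single configuration object drives [run_pipeline()]; every stochastic
#' stage receives its own seed derived deterministically from the master
#' seed and the stage name, so reruns with the same configuration are
#' byte-identical. Any element can be overridden via \code{...} using the
#' same nested-list structure; stage toggles live under \code{stages}.
#'
#' @param seed Master seed.
#' @param ... Named overrides merged over the defaults (one level deep per
#'   section, e.g. \code{library = list(n_clones = 200)}).
#' @return A \code{run_config} list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    stages = list(simulate = TRUE, repertoire = TRUE, screen = TRUE,
                  enrich = TRUE, triage_knn = TRUE, triage_conv = TRUE,
                  aggregate = TRUE, assays = FALSE),
    library = list(n_clones = 500, pool_sizes = c(20, 20, 40),
                   cdr_lengths = c(7, 6, 12), liability_fraction = 0.05),
    affinity = list(binder_fraction = 0.1, binder_motif = "WGWG"),
    panning = list(n_rounds = 4, antigen_conc = c(100, 50, 25, 10) * 1e-9,
                   reads_per_round = 5000),
    sequencing = list(error_rate = 0.001, spike_fraction = 0.01),
    enrichment = list(n_top_clonotypes = 20, variants_per_clonotype = 3,
                      pseudocount = 0.5),
    spr = list(n_labels = 100, flip_rate = 0.05),
    knn = list(pca_components = c(2, 5, 10, 15), k_neighbors = c(3, 5, 7, 9),
               beta = 1, cv_folds = 5),
    conv = list(n_filters = 16, kernel_size = 5, hidden = 32, epochs = 30,
                threshold = 0.5, n_clusters = 20),
    assays = list(competition_csv = NULL, competition_threshold = 0.30,
                  peptide_csv = NULL, tgi_csv = NULL)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys follow the [run_config()] structure.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(list(seed = raw$seed %||% 1),
                        raw[setdiff(names(raw), "seed")]))
}

#' Run the panning-to-candidates pipeline
#'
#' Executes the enabled stages in order: simulate (synthetic campaign +
#' per-round FASTQ), repertoire (anchor/annotation of rounds 3 and 4),
#' screen (liability filter), enrich (clonotype enrichment candidates),
#' triage_knn / triage_conv (ML candidates), aggregate (union with
#' provenance), and optional assays on user-supplied CSV inputs. A manifest
#' (JSON) records parameters, per-stage record accounting (records in =
#' records out + records filtered at every stage), output-file checksums,
#' and the package version. A stage failure halts the run with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  if (isTRUE(config$stages$assays)) {
    for (f in c("competition_csv", "peptide_csv", "tgi_csv")) {
      p <- config$assays[[f]]
      if (!is.null(p) && !file.exists(p)) {
        stop("validation error: missing input path: ", p)
      }
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("panscreen")),
                   created = format(Sys.time(), tz = "UTC"),
                   seed = config$seed,
                   parameters = unclass(config),
                   stages = list())
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  campaign <- NULL
  variants <- NULL
  kept <- NULL
  enr <- NULL
  candidates <- list()

  if (isTRUE(config$stages$simulate)) {
    stage("simulate", {
      design <- vhh_library_design(
        pool_sizes = config$library$pool_sizes,
        cdr_lengths = config$library$cdr_lengths,
        liability_fraction = config$library$liability_fraction,
        seed = stage_seed(config$seed, "design")
      )
      campaign <- generate_library(design, config$library$n_clones,
                                   seed = stage_seed(config$seed, "library"))
      campaign <- assign_affinities(
        campaign,
        binder_fraction = config$affinity$binder_fraction,
        binder_motif = config$affinity$binder_motif,
        seed = stage_seed(config$seed, "affinity")
      )
      pan_cfg <- panning_config(
        n_rounds = config$panning$n_rounds,
        antigen_conc = config$panning$antigen_conc,
        reads_per_round = config$panning$reads_per_round,
        seed = stage_seed(config$seed, "panning")
      )
      campaign <- simulate_panning(campaign, pan_cfg)
      for (r in c(config$panning$n_rounds - 1L, config$panning$n_rounds)) {
        f <- file.path(outdir, paste0("R", r, ".fastq"))
        emit_fastq(campaign, r, f,
                   error_rate = config$sequencing$error_rate,
                   spike_fraction = config$sequencing$spike_fraction,
                   seed = stage_seed(config$seed, paste0("fastq", r)))
        files <- c(files, f)
      }
      tf <- file.path(outdir, "truth.json")
      write_campaign_truth(campaign, tf)
      cf <- file.path(outdir, "counts.csv")
      utils::write.csv(cbind(clone_id = rownames(campaign$counts),
                             as.data.frame(campaign$counts)),
                       cf, row.names = FALSE)
      files <- c(files, tf, cf)
      manifest$stages$simulate <- list(
        n_clones = nrow(campaign$clones),
        n_binders = sum(campaign$clones$is_binder),
        n_planted_liabilities = sum(!is.na(campaign$clones$planted_liability))
      )
    })
  }

  if (isTRUE(config$stages$repertoire)) {
    stage("repertoire", {
      r3 <- config$panning$n_rounds - 1L
      r4 <- config$panning$n_rounds
      per_round <- lapply(c(r3, r4), function(r) {
        annotate_reads(file.path(outdir, paste0("R", r, ".fastq")))
      })
      acc <- lapply(per_round, attr, "accounting")
      for (a in acc) {
        stopifnot(a[["total"]] ==
                    a[["anchorless"]] + a[["annotated"]] + a[["flagged"]])
      }
      tab <- lapply(per_round, function(ann) {
        ok <- ann[ann$annotated & lengths(ann$qc_flags) == 0, , drop = FALSE]
        agg <- dereplicate(ok$aa)
        agg$idx <- match(agg$aa, ok$aa)
        list(ann = ok, agg = agg)
      })
      all_aa <- sort(union(tab[[1]]$agg$aa, tab[[2]]$agg$aa))
      first <- rbind(tab[[1]]$ann, tab[[2]]$ann)
      firsti <- match(all_aa, first$aa)
      variants <- tibble::tibble(
        clone_id = sprintf("var%05d", seq_along(all_aa)),
        aa = all_aa,
        nt = first$nt[firsti],
        cdr3 = first$cdr3[firsti],
        regions = first$regions[firsti],
        aa_offset_nt = 0L,
        count_r3 = tab[[1]]$agg$count[match(all_aa, tab[[1]]$agg$aa)],
        count_r4 = tab[[2]]$agg$count[match(all_aa, tab[[2]]$agg$aa)]
      )
      variants$count_r3[is.na(variants$count_r3)] <- 0L
      variants$count_r4[is.na(variants$count_r4)] <- 0L
      vf <- file.path(outdir, "variants.csv")
      utils::write.csv(variants[, c("clone_id", "aa", "cdr3",
                                    "count_r3", "count_r4")],
                       vf, row.names = FALSE)
      files <- c(files, vf)
      manifest$stages$repertoire <- list(
        r3 = as.list(acc[[1]]), r4 = as.list(acc[[2]]),
        unique_variants = nrow(variants)
      )
    })
  }

  if (isTRUE(config$stages$screen)) {
    stage("screen", {
      res <- filter_library(variants)
      kept <- res$kept
      rf <- file.path(outdir, "liability_report.csv")
      utils::write.csv(res$report, rf, row.names = FALSE)
      files <- c(files, rf)
      stopifnot(nrow(res$kept) + nrow(res$removed) == nrow(variants))
      manifest$stages$screen <- list(
        records_in = nrow(variants),
        records_out = nrow(res$kept),
        records_filtered = nrow(res$removed)
      )
    })
  } else {
    kept <- variants
  }

  if (isTRUE(config$stages$enrich)) {
    stage("enrich", {
      ct <- assign_clonotypes(kept)
      table <- enrichment_table(ct$clonotypes,
                                pseudocount = config$enrichment$pseudocount)
      enr <- list(clonotypes = ct, table = table)
      cand <- select_enrichment_candidates(
        table, ct$variants,
        n_top_clonotypes = config$enrichment$n_top_clonotypes,
        variants_per_clonotype = config$enrichment$variants_per_clonotype
      )
      candidates$enrichment <- cand$aa
      ef <- file.path(outdir, "enrichment.csv")
      utils::write.csv(table, ef, row.names = FALSE)
      files <- c(files, ef)
      manifest$stages$enrich <- list(
        n_clonotypes = nrow(ct$clonotypes),
        n_candidates = length(unique(cand$aa))
      )
    })
  }

  training <- NULL
  if (isTRUE(config$stages$triage_knn) || isTRUE(config$stages$triage_conv)) {
    stage("training_set", {
      spr <- simulate_spr_labels(campaign,
                                 n_labels = config$spr$n_labels,
                                 flip_rate = config$spr$flip_rate,
                                 seed = stage_seed(config$seed, "spr"))
      enriched_pos <- if (!is.null(enr)) {
        top <- utils::head(enr$table$clonotype_id,
                           config$enrichment$n_top_clonotypes)
        enr$clonotypes$variants$aa[enr$clonotypes$variants$clonotype_id %in% top]
      } else {
        character(0)
      }
      training <- build_training_set(
        spr_labels = spr,
        round4_enriched = enriched_pos,
        library_sample = campaign$clones$aa,
        neg_sample_size = config$spr$n_labels,
        seed = stage_seed(config$seed, "negatives")
      )
    })
  }

  apply_aa <- if (!is.null(kept)) kept$aa[kept$count_r4 > 0] else character(0)

  if (isTRUE(config$stages$triage_knn)) {
    stage("triage_knn", {
      model <- tune_knn(training,
                        grid = list(pca_components = config$knn$pca_components,
                                    k_neighbors = config$knn$k_neighbors),
                        beta = config$knn$beta,
                        cv_folds = config$knn$cv_folds,
                        seed = stage_seed(config$seed, "knn"))
      pred <- predict(model, apply_aa, type = "class")
      candidates$knn <- apply_aa[pred]
      kf <- file.path(outdir, "knn_candidates.csv")
      utils::write.csv(data.frame(aa = candidates$knn), kf, row.names = FALSE)
      files <- c(files, kf)
      manifest$stages$triage_knn <- list(
        pca_components = model$pca_components,
        k_neighbors = model$k_neighbors,
        cv_fbeta = model$best_fbeta,
        n_candidates = length(candidates$knn)
      )
    })
  }

  if (isTRUE(config$stages$triage_conv)) {
    stage("triage_conv", {
      model <- train_conv_classifier(
        training,
        n_filters = config$conv$n_filters,
        kernel_size = config$conv$kernel_size,
        hidden = config$conv$hidden,
        epochs = config$conv$epochs,
        seed = stage_seed(config$seed, "conv")
      )
      binders <- predict_binders(model, apply_aa,
                                 threshold = config$conv$threshold)
      div <- if (nrow(binders) > 0) {
        diversify(binders, min(config$conv$n_clusters, nrow(binders)))
      } else {
        tibble::tibble(aa = character(0), probability = numeric(0),
                       cluster_id = integer(0))
      }
      candidates$conv <- div$aa
      cf <- file.path(outdir, "conv_candidates.csv")
      utils::write.csv(div, cf, row.names = FALSE)
      files <- c(files, cf)
      manifest$stages$triage_conv <- list(
        best_epoch = model$best_epoch, val_f1 = model$val_f1,
        n_thresholded = nrow(binders), n_candidates = nrow(div)
      )
    })
  }

  if (isTRUE(config$stages$aggregate)) {
    stage("aggregate", {
      agg <- do.call(aggregate_candidates, candidates)
      af <- file.path(outdir, "candidates.csv")
      utils::write.csv(
        data.frame(aa = agg$aa,
                   provenance = vapply(agg$provenance, paste,
                                       character(1), collapse = ";")),
        af, row.names = FALSE)
      files <- c(files, af)
      manifest$stages$aggregate <- list(
        per_workflow = lapply(candidates, function(x) length(unique(x))),
        aggregated_unique = nrow(agg)
      )
    })
  }

  if (isTRUE(config$stages$assays)) {
    stage("assays", {
      res <- list()
      if (!is.null(config$assays$competition_csv)) {
        m <- as.matrix(utils::read.csv(config$assays$competition_csv,
                                       row.names = 1, check.names = FALSE))
        bins <- assign_bins(binarize_competition(
          m, config$assays$competition_threshold))
        bf <- file.path(outdir, "bins.csv")
        utils::write.csv(bins, bf, row.names = FALSE)
        files <- c(files, bf)
        res$n_bins <- attr(bins, "n_bins")
      }
      if (!is.null(config$assays$peptide_csv)) {
        pep <- utils::read.csv(config$assays$peptide_csv)
        fp <- footprint_table(pep)
        ff <- file.path(outdir, "footprint.csv")
        utils::write.csv(fp, ff, row.names = FALSE)
        files <- c(files, ff)
        res$n_peptides <- nrow(fp)
      }
      if (!is.null(config$assays$tgi_csv)) {
        tg <- utils::read.csv(config$assays$tgi_csv)
        tg$tgi_percent <- compute_tgi(tg$t0, tg$tt, tg$c0, tg$ct)
        tf <- file.path(outdir, "tgi.csv")
        utils::write.csv(tg, tf, row.names = FALSE)
        files <- c(files, tf)
        res$n_groups <- nrow(tg)
      }
      manifest$stages$assays <- res
    })
  }

  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Mirrors a per-workflow accounting table: one row per candidate workflow
#' with the stage counts leading to it.
#'
#' @param outdir Run directory containing \code{manifest.json}.
#' @return A tibble with one row per workflow (\code{enrichment},
#'   \code{knn}, \code{conv}) and columns \code{reads_in},
#'   \code{annotated}, \code{liability_removed}, \code{clonotypes},
#'   \code{candidates}, \code{aggregated_unique}.
#' @export
summarize_run <- function(outdir) {
  mf <- file.path(outdir, "manifest.json")
  if (!file.exists(mf)) stop("manifest not found in ", outdir)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  s <- m$stages
  reads_in <- if (!is.null(s$repertoire)) {
    s$repertoire$r3$total + s$repertoire$r4$total
  } else {
    NA_integer_
  }
  annotated <- if (!is.null(s$repertoire)) {
    s$repertoire$r3$annotated + s$repertoire$r4$annotated
  } else {
    NA_integer_
  }
  removed <- if (!is.null(s$screen)) s$screen$records_filtered else NA_integer_
  cts <- if (!is.null(s$enrich)) s$enrich$n_clonotypes else NA_integer_
  agg <- if (!is.null(s$aggregate)) s$aggregate$aggregated_unique else NA_integer_
  cand <- c(
    enrichment = if (!is.null(s$enrich)) s$enrich$n_candidates else 0L,
    knn = if (!is.null(s$triage_knn)) s$triage_knn$n_candidates else 0L,
    conv = if (!is.null(s$triage_conv)) s$triage_conv$n_candidates else 0L
  )
  tibble::tibble(
    workflow = names(cand),
    reads_in = reads_in,
    annotated = annotated,
    liability_removed = removed,
    clonotypes = cts,
    candidates = as.integer(cand),
    aggregated_unique = agg
  )
}
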