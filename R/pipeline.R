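#' @name pipeline
#' @title End-to-end clustering pipeline
#'
#' @description
#' [run_pipeline()] orchestrates the full analysis: parse and featurize the
#' library, engineer the fused feature table, train the requested
#' autoencoder embeddings, scan cluster counts by Silhouette, cluster at
#' the selected k with K-means and/or BIRCH, evaluate the three internal
#' indices, and write visualizations. Every stage writes its artifact into
#' the output directory and is skipped on rerun when the artifact already
#' exists, so interrupted runs resume; all artifacts embed the
#' configuration hash and a directory written under a different
#' configuration is refused.
NULL

#' Pipeline configuration
#'
#' @param input Path to a `.smi`/`.csv` molecule file, or `NULL` when
#'   `molecules` is given directly.
#' @param molecules Optional data frame with `id` and `smiles`, used instead
#'   of `input`.
#' @param out_dir Artifact directory (created if missing).
#' @param smiles_col,id_col CSV column mapping.
#' @param descriptor_set Descriptor names (default: full collection).
#' @param n_local_components Local PCA components (default 50).
#' @param latent_dims Latent sizes to sweep (default `c(16, 32, 64)`).
#' @param embedder `"AE"`, `"VAE"`, `"both"` or `"none"`.
#' @param beta VAE KL weight.
#' @param epochs,batch_size Training parameters.
#' @param k_grid Candidate cluster counts (default `seq(5, 200, by = 5)`).
#' @param clusterers Subset of `c("kmeans", "birch")`.
#' @param subsample Silhouette-scan subsample cap (default 10000).
#' @param include_raw Also cluster the raw fused features (default `TRUE`).
#' @param tsne_max Maximum points sent to t-SNE (default 2000).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, molecules = NULL,
                            out_dir = "molcluster_run",
                            smiles_col = "smiles", id_col = "id",
                            descriptor_set = NULL,
                            n_local_components = 50L,
                            latent_dims = c(16L, 32L, 64L),
                            embedder = c("both", "AE", "VAE", "none"),
                            beta = 1, epochs = 100L, batch_size = 256L,
                            k_grid = seq(5L, 200L, by = 5L),
                            clusterers = c("kmeans", "birch"),
                            subsample = 10000L, include_raw = TRUE,
                            tsne_max = 2000L, seed = 1L) {
  embedder <- match.arg(embedder)
  clusterers <- match.arg(clusterers, several.ok = TRUE)
  if (is.null(input) && is.null(molecules)) {
    stop("either 'input' or 'molecules' is required", call. = FALSE)
  }
  structure(list(
    input = input, molecules = molecules, out_dir = out_dir,
    smiles_col = smiles_col, id_col = id_col,
    descriptor_set = descriptor_set,
    n_local_components = as.integer(n_local_components),
    latent_dims = as.integer(latent_dims), embedder = embedder,
    beta = beta, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), k_grid = as.integer(k_grid),
    clusterers = clusterers, subsample = as.integer(subsample),
    include_raw = isTRUE(include_raw), tsne_max = as.integer(tsne_max),
    seed = as.integer(seed)), class = "pipeline_config")
}

.write_csv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
}

.read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.write_json_stamped <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @param stop_after Run only the leading stages: `"features"`,
#'   `"embeddings"`, `"report"` or `"all"` (default). Later invocations
#'   resume from the written artifacts.
#' @return Invisibly, a list with the evaluation `report` (data frame in
#'   the method / #clusters / three-indices layout), the per-representation
#'   results and the artifact directory.
#' @export
run_pipeline <- function(cfg, quiet = FALSE,
                         stop_after = c("all", "features", "embeddings",
                                        "report")) {
  stop_after <- match.arg(stop_after)
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[molcluster] ", ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash_cfg <- cfg
  hash_cfg$molecules <- NULL  # content covered by molecules.csv itself
  hash <- .config_hash(unclass(hash_cfg))
  cfg_path <- file.path(cfg$out_dir, "run_config.json")
  if (file.exists(cfg_path)) {
    prev <- jsonlite::read_json(cfg_path)
    if (!identical(prev$config_hash, hash)) {
      stop("output directory ", cfg$out_dir, " holds artifacts from a ",
           "different configuration (hash ", prev$config_hash, " != ", hash,
           "); use a fresh directory", call. = FALSE)
    }
  } else {
    .write_json_stamped(unclass(hash_cfg), cfg_path, hash)
  }
  path <- function(...) file.path(cfg$out_dir, ...)

  # --- stage 1: parse + featurize ------------------------------------------
  mol_path <- path("molecules.csv")
  if (file.exists(mol_path)) {
    say("resume: molecules.csv")
    mol_df <- .read_csv_stamped(mol_path)
  } else {
    mol_df <- if (!is.null(cfg$molecules)) cfg$molecules
              else read_smiles_file(cfg$input, cfg$smiles_col, cfg$id_col)
    .write_csv_stamped(mol_df, mol_path, hash)
  }
  say("parsing ", nrow(mol_df), " molecules")
  mols <- parse_molecules(mol_df)

  ft_path <- path("feature_table.csv")
  meta_path <- path("feature_metadata.json")
  if (file.exists(ft_path)) {
    say("resume: feature_table.csv")
    ft_df <- .read_csv_stamped(ft_path)
    ft_values <- as.matrix(ft_df[, -1, drop = FALSE])
    rownames(ft_values) <- ft_df[[1]]
    colnames(ft_values) <- colnames(ft_df)[-1]
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    prov <- meta$provenance
  } else {
    say("featurizing and engineering features")
    ft <- engineer_features(mols, cfg$n_local_components, cfg$descriptor_set)
    ft_values <- ft$values
    prov <- ft$provenance
    meta <- attr(ft, "metadata")
    meta$provenance <- prov
    out_df <- data.frame(id = rownames(ft_values), ft_values,
                         check.names = FALSE)
    .write_csv_stamped(out_df, ft_path, hash)
    .write_json_stamped(meta, meta_path, hash)
  }
  say("feature table: ", nrow(ft_values), " x ", ncol(ft_values))
  if (stop_after == "features") {
    return(invisible(list(out_dir = cfg$out_dir, config_hash = hash)))
  }

  # --- stage 2: embeddings --------------------------------------------------
  reps <- list()
  if (cfg$include_raw) {
    reps[["raw features"]] <- ft_values
  }
  emb_types <- switch(cfg$embedder, both = c("AE", "VAE"), none = character(0),
                      cfg$embedder)
  dir.create(path("embeddings"), showWarnings = FALSE)
  for (ty in emb_types) {
    for (d in cfg$latent_dims) {
      tag <- paste0(ty, d)
      emb_path <- path("embeddings", paste0("embedding_", tag, ".csv"))
      if (file.exists(emb_path)) {
        say("resume: embedding ", tag)
        df <- .read_csv_stamped(emb_path)
        emb <- as.matrix(df[, -1, drop = FALSE])
        rownames(emb) <- df[[1]]
      } else {
        say("training ", ty, " with d = ", d)
        fit <- train_autoencoder(
          ft_values,
          training_config(latent_dim = d, beta = cfg$beta,
                          epochs = cfg$epochs, batch_size = cfg$batch_size,
                          seed = cfg$seed + d),
          variational = (ty == "VAE"))
        emb <- unclass(fit$embedding)
        .write_csv_stamped(data.frame(id = rownames(ft_values), emb,
                                      check.names = FALSE),
                           emb_path, hash)
        .write_csv_stamped(data.frame(epoch = seq_along(fit$loss_history),
                                      loss = fit$loss_history),
                           path("embeddings", paste0("loss_", tag, ".csv")),
                           hash)
      }
      reps[[paste0(ty, " (", d, ")")]] <- emb
    }
  }

  if (stop_after == "embeddings") {
    return(invisible(list(out_dir = cfg$out_dir, config_hash = hash)))
  }

  # --- stage 3: scan, cluster, evaluate ------------------------------------
  dir.create(path("scans"), showWarnings = FALSE)
  dir.create(path("clusters"), showWarnings = FALSE)
  results <- list()
  for (rep_name in names(reps)) {
    X <- reps[[rep_name]]
    tag <- gsub("[^A-Za-z0-9]", "", rep_name)
    for (cl in cfg$clusterers) {
      rtag <- paste0(cl, "_", tag)
      clu_name <- if (cl == "kmeans") "K-means" else "BIRCH"
      row_name <- if (rep_name == "raw features")
        paste0(clu_name, " (raw features)")
        else paste0(rep_name, " + ", clu_name)
      assign_path <- path("clusters", paste0("assignment_", rtag, ".csv"))
      scan_path <- path("scans", paste0("scan_", rtag, ".csv"))
      if (file.exists(assign_path)) {
        say("resume: clustering ", row_name)
        adf <- .read_csv_stamped(assign_path)
        labels <- adf$cluster
        k <- length(unique(labels))
        fit <- structure(list(labels = labels, k = k,
                              centroids = NULL, inertia = NA_real_,
                              method = cl), class = "cluster_assignment")
      } else {
        say("scanning k for ", row_name)
        scan <- scan_k(X, k_grid = cfg$k_grid, method = cl,
                       seed = cfg$seed, subsample = cfg$subsample,
                       cache_file = scan_path)
        k <- suppressMessages(select_k(scan))
        grDevices::png(path("scans", paste0("scan_", rtag, ".png")),
                       width = 800, height = 500)
        plot(scan, selected = k)
        grDevices::dev.off()
        say("clustering ", row_name, " at k = ", k)
        fit <- if (cl == "kmeans") kmeans_cluster(X, k, seed = cfg$seed)
               else birch_cluster(X, k)
        .write_csv_stamped(data.frame(id = rownames(ft_values),
                                      cluster = fit$labels),
                           assign_path, hash)
      }
      idx <- evaluate_all(X, fit$labels)
      results[[row_name]] <- list(k = fit$k, indices = idx,
                                  representation = rep_name,
                                  clusterer = cl, fit = fit, X = X)
    }
  }
  report <- index_report(results)
  .write_csv_stamped(report, path("report.csv"), hash)
  .write_json_stamped(
    list(report = report), path("metrics.json"), hash)
  if (stop_after == "report") {
    return(invisible(list(report = report, results = results,
                          out_dir = cfg$out_dir, config_hash = hash)))
  }

  # --- stage 4: visualize ---------------------------------------------------
  best <- results[[which.max(report$silhouette)]]
  say("best: ", report$method[which.max(report$silhouette)],
      " (silhouette ", round(max(report$silhouette), 3), ")")
  n <- nrow(best$X)
  vis_idx <- if (n > cfg$tsne_max)
    .with_seed(cfg$seed, sort(sample.int(n, cfg$tsne_max))) else seq_len(n)
  perp <- min(30, max(2, floor((length(vis_idx) - 1) / 4)))
  coords <- tsne_2d(best$X[vis_idx, , drop = FALSE], perplexity = perp,
                    seed = cfg$seed)
  grDevices::png(path("tsne_clusters.png"), width = 900, height = 700)
  plot_tsne_clusters(coords, best$fit$labels[vis_idx])
  grDevices::dev.off()
  grDevices::png(path("cluster_sizes.png"), width = 900, height = 500)
  plot_cluster_sizes(best$fit)
  grDevices::dev.off()

  # Tanimoto heatmap of a few molecules from a few clusters
  picked <- .with_seed(cfg$seed, {
    lev <- utils::head(sort(unique(best$fit$labels)), 5L)
    unlist(lapply(lev, function(q) {
      members <- which(best$fit$labels == q)
      sample(members, min(4L, length(members)))
    }))
  })
  tm <- tanimoto_matrix(mols[picked])
  .write_csv_stamped(data.frame(id = rownames(tm), tm, check.names = FALSE),
                     path("tanimoto_matrix.csv"), hash)
  grDevices::png(path("tanimoto_heatmap.png"), width = 800, height = 800)
  plot_tanimoto_heatmap(tm, groups = best$fit$labels[picked])
  grDevices::dev.off()

  say("done; artifacts in ", cfg$out_dir)
  invisible(list(report = report, results = results, out_dir = cfg$out_dir,
                 config_hash = hash))
}
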