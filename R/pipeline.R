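#' Pipeline run configuration
#'
#' Collects every path and parameter of the reconstruction pipeline.
#' Referenced input paths are validated before any stage runs.
#'
#' @param fastq_dir Directory of per-tile spatial-barcode FASTQ files.
#' @param spatial_r1,spatial_r2 Paired spatial-library FASTQ paths.
#' @param out_dir Output directory.
#' @param gene_tags Path to the gene-tag TSV (gene_id, tag) for the internal
#'   quantification path, or `NULL` when importing an external matrix.
#' @param mtx,mtx_barcodes,mtx_features External count-matrix triplet file
#'   and companion lists (used instead of internal quantification when set).
#' @param pattern_template Barcode template string (see [barcode_pattern()]).
#' @param exclude_tiles Integer tile ids noted for exclusion.
#' @param tile_width,tile_height Tile extent in raw units.
#' @param bin_size_px Density-image bin size in raw units.
#' @param n_fiducials Expected fiducials per tile.
#' @param radius_outer,radius_inner Circle radius ranges in pixels.
#' @param calibration_nm,calibration_raw Paired spacing measurements for
#'   [calibrate_scale()].
#' @param offset_axis Even-swath offset axis.
#' @param bin_sizes Native bin edges to produce.
#' @param min_hits,n_id_reads Tile-identification parameters.
#' @param seed Seed recorded in provenance.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fastq_dir, spatial_r1, spatial_r2, out_dir,
                       gene_tags = NULL,
                       mtx = NULL, mtx_barcodes = NULL, mtx_features = NULL,
                       pattern_template = paste0("CTCTTCCGATCT",
                                                 "NNVNNVNNVNNVNNVNNNNN"),
                       exclude_tiles = integer(0),
                       tile_width = 5000, tile_height = 5000,
                       bin_size_px = 25L, n_fiducials = 4L,
                       radius_outer = c(40, 80), radius_inner = c(15, 30),
                       calibration_nm = 25000, calibration_raw = 728,
                       offset_axis = "y",
                       bin_sizes = c(728L, 1456L, 2912L),
                       min_hits = 10L, n_id_reads = 1000000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("fastq_dir", "spatial_r1", "spatial_r2"))
    if (!file.exists(cfg[[p]]))
      stop("validation error: ", p, " does not exist: ", cfg[[p]])
  if (is.null(cfg$mtx) && is.null(cfg$gene_tags))
    stop("validation error: need either gene_tags (internal path) or mtx (import path)")
  for (p in c("gene_tags", "mtx", "mtx_barcodes", "mtx_features"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("validation error: ", p, " does not exist: ", cfg[[p]])
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

md5_of <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  as.list(h)
}

# run one stage with hash-based resumability
run_stage <- function(state, name, inputs, outputs, fn) {
  man <- state$manifest
  prev <- man$stages[[name]]
  in_hash <- md5_of(inputs)
  if (!is.null(prev) && identical(prev$inputs, in_hash) &&
      all(file.exists(outputs)) &&
      identical(md5_of(outputs), prev$outputs)) {
    message("[", name, "] up to date, skipped")
    return(state)
  }
  message("[", name, "] running")
  info <- tryCatch(fn(), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  state$manifest$stages[[name]] <- list(inputs = in_hash,
                                        outputs = md5_of(outputs),
                                        info = info)
  state
}

#' Run the full reconstruction pipeline
#'
#' Executes the stages in order: per-tile indexing, fiducial detection,
#' stitching, tissue-tile identification, whitelist construction,
#' quantification (internal) or matrix import, GEM assembly, and binning
#' with QC. Every stage persists its outputs under `out_dir` and records
#' input/output hashes in `manifest.json`; rerunning with unchanged inputs
#' skips completed stages.
#'
#' @param config A [run_config()].
#' @param stop_after Optional stage name (`index`, `fiducials`, `stitch`,
#'   `select`, `whitelist`, `quantify`/`import`, `gem`, `bin`); the pipeline
#'   halts once that stage has completed.
#' @return Invisibly, the manifest list (also written as
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, stop_after = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("index", "fiducials", "stitch", "select", "whitelist",
              "quant", "gem", "bin"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  man_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else list(stages = list())
  manifest$config <- config[!vapply(config, is.null, logical(1))]
  state <- list(manifest = manifest)
  finish <- function(state) {
    state$manifest$seed <- config$seed
    jsonlite::write_json(state$manifest, man_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(state$manifest)
  }
  halt_here <- function(stage) !is.null(stop_after) &&
    identical(stop_after, stage)
  pattern <- barcode_pattern(config$pattern_template)

  hdmi_files <- list.files(config$fastq_dir,
                           pattern = "^hdmi_tile_\\d+\\.fastq(\\.gz)?$",
                           full.names = TRUE)
  index_dir <- file.path(out, "index")
  stats_path <- file.path(index_dir, "index_stats.tsv")

  state <- run_stage(state, "index", hdmi_files, stats_path, function() {
    idx <- index_fastq_dir(config$fastq_dir, pattern,
                           exclude_tiles = config$exclude_tiles)
    for (x in idx) {
      write_index(x, file.path(index_dir, sprintf("tile_%d.nvst", x$tile_id)))
      write_index(x, file.path(index_dir,
                               sprintf("tile_%d_subset.nvst", x$tile_id)),
                  what = "subset")
    }
    st <- data.table::rbindlist(lapply(idx, function(x)
      data.table::data.table(tile_id = x$tile_id, total = x$stats[["total"]],
                             valid = x$stats[["valid"]],
                             invalid = x$stats[["invalid"]])))
    data.table::fwrite(st, stats_path, sep = "\t")
    list(tiles = length(idx), valid_reads = sum(st$valid))
  })

  if (halt_here("index")) return(finish(state))

  load_indexes <- function() {
    files <- list.files(index_dir, pattern = "^tile_\\d+\\.nvst$",
                        full.names = TRUE)
    idx <- lapply(files, read_index)
    names(idx) <- vapply(idx, function(x) as.character(x$tile_id), "")
    idx[order(as.integer(names(idx)))]
  }

  index_files <- function(suffix = "")
    list.files(index_dir, pattern = paste0("^tile_\\d+", suffix, "\\.nvst$"),
               full.names = TRUE)

  centroids_path <- file.path(out, "fiducials", "centroids.tsv")
  state <- run_stage(state, "fiducials", index_files(), centroids_path,
                     function() {
    idx <- load_indexes()
    fids <- lapply(idx, detect_tile_fiducials,
                   bin_size = config$bin_size_px,
                   width = config$tile_width, height = config$tile_height,
                   n_fiducials = config$n_fiducials,
                   radius_ranges = list(outer = config$radius_outer,
                                        inner = config$radius_inner))
    cts <- data.table::rbindlist(lapply(fids, function(f) {
      parts <- split_tile_id(f$tile_id)
      data.table::data.table(tile_id = f$tile_id, swath = parts$swath,
                             row = parts$row, cx = f$centroid[1],
                             cy = f$centroid[2], complete = f$complete)
    }))
    cts <- interpolate_missing(cts)
    data.table::fwrite(cts, centroids_path, sep = "\t")
    list(complete_tiles = sum(cts$complete),
         interpolated = sum(cts$interpolated))
  })

  if (halt_here("fiducials")) return(finish(state))

  global_path <- file.path(out, "stitch", "global_index.tsv")
  offsets_path <- file.path(out, "stitch", "offsets.tsv")
  state <- run_stage(state, "stitch", c(index_files(), centroids_path),
                     c(global_path, offsets_path), function() {
    idx <- load_indexes()
    cts <- data.table::fread(centroids_path)
    cal <- calibrate_scale(config$calibration_nm, config$calibration_raw)
    offsets <- compute_tile_offsets(cts,
                                    c(config$tile_width, config$tile_height),
                                    offset_axis = config$offset_axis)
    global <- apply_offsets(idx, offsets, cal)
    data.table::fwrite(offsets, offsets_path, sep = "\t")
    write_global_index(global, global_path)
    list(records = nrow(global), nm_per_unit = cal$nm_per_unit,
         collisions = attr(global, "collisions"))
  })

  if (halt_here("stitch")) return(finish(state))

  load_global <- function() {
    gi <- data.table::fread(global_path, skip = "barcode")
    k <- as.numeric(sub("^# nm_per_unit=", "",
                        grep("^# nm_per_unit=", readLines(global_path, 5),
                             value = TRUE)))
    data.table::setattr(gi, "nm_per_unit", k)
    gi
  }

  tiles_path <- file.path(out, "select", "tiles.tsv")
  state <- run_stage(state, "select",
                     c(config$spatial_r1, index_files("_subset")),
                     tiles_path, function() {
    subs <- lapply(index_files("_subset"), read_index)
    names(subs) <- vapply(subs, function(x) as.character(x$tile_id), "")
    sel <- identify_tiles(config$spatial_r1, subs,
                          n_reads = config$n_id_reads,
                          min_hits = config$min_hits)
    hits <- attr(sel, "hits")
    data.table::fwrite(data.table::data.table(
      tile_id = as.integer(names(hits)), hits = as.integer(hits),
      selected = as.integer(names(hits)) %in% sel), tiles_path, sep = "\t")
    list(selected = as.integer(sel))
  })

  if (halt_here("select")) return(finish(state))

  wl_path <- file.path(out, "whitelist", "whitelist.tsv")
  state <- run_stage(state, "whitelist", c(global_path, tiles_path),
                     wl_path, function() {
    sel <- data.table::fread(tiles_path)[selected == TRUE, tile_id]
    wl <- build_whitelist(load_global(), sel)
    data.table::fwrite(wl$entries, wl_path, sep = "\t")
    list(entries = nrow(wl$entries), collisions = wl$collisions)
  })

  if (halt_here("whitelist")) return(finish(state))

  load_whitelist <- function() {
    entries <- data.table::fread(wl_path)
    structure(list(entries = entries, collisions = NA_integer_,
                   tiles = unique(entries$tile_id)),
              class = "nova_whitelist")
  }

  counts_path <- file.path(out, "quant", "counts.tsv")
  if (is.null(config$mtx)) {
    state <- run_stage(state, "quantify",
                       c(config$spatial_r1, config$spatial_r2, wl_path,
                         config$gene_tags),
                       counts_path, function() {
      q <- quantify(config$spatial_r1, config$spatial_r2, load_whitelist(),
                    data.table::fread(config$gene_tags))
      data.table::fwrite(q$counts, counts_path, sep = "\t")
      as.list(q$stats)
    })
  } else {
    state <- run_stage(state, "import",
                       c(config$mtx, config$mtx_barcodes,
                         config$mtx_features, wl_path),
                       counts_path, function() {
      imp <- import_counts(config$mtx, config$mtx_barcodes,
                           config$mtx_features, load_whitelist())
      data.table::fwrite(imp$counts, counts_path, sep = "\t")
      list(records = nrow(imp$counts), dropped = imp$dropped)
    })
  }

  if (halt_here("quantify") || halt_here("import"))
    return(finish(state))

  gem_path <- file.path(out, "gem", "output.gem")
  state <- run_stage(state, "gem", c(counts_path, wl_path), gem_path,
                     function() {
    cal <- calibrate_scale(config$calibration_nm, config$calibration_raw)
    counts <- data.table::fread(counts_path)
    write_gem(counts, load_whitelist(), cal, gem_path)
    list(molecules = sum(counts$count))
  })

  if (halt_here("gem")) return(finish(state))

  bin_outputs <- unlist(lapply(config$bin_sizes, function(s)
    file.path(out, "bin", paste0("bin", s, c(".mtx", "_qc.tsv")))))
  state <- run_stage(state, "bin", gem_path, bin_outputs, function() {
    gem <- read_gem(gem_path)
    cal <- calibrate_scale(config$calibration_nm, config$calibration_raw)
    info <- list()
    for (s in config$bin_sizes) {
      b <- bin_counts(gem, s, cal$nm_per_unit)
      bf <- qc_filter(b)
      bn <- normalize_log(bf)
      sm <- summarize_bins(bf)
      prefix <- file.path(out, "bin", paste0("bin", s))
      write_binned(bf, prefix)
      data.table::fwrite(sm$per_bin, paste0(prefix, "_qc.tsv"), sep = "\t")
      info[[paste0("bin", s)]] <- list(bins_kept = bf$qc$kept,
                                       bins_removed = bf$qc$removed,
                                       median_genes = sm$median_genes,
                                       median_umis = sm$median_umis)
    }
    info
  })

  finish(state)
}
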