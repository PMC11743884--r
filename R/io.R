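#' Read and write connectome matrices as delimited tables
#'
#' Connectomes travel as square tab-separated tables with a header row of
#' region labels and the labels repeated in the first column.
#'
#' @param w Labelled symmetric matrix.
#' @param path File path.
#' @return `read_connectome` returns the labelled matrix;
#'   `write_connectome` returns `path` invisibly.
#' @export
write_connectome <- function(w, path) {
  df <- data.frame(region = rownames(w), w, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a node-volume table
#'
#' @param volumes Named numeric vector.
#' @param path File path.
#' @export
write_node_volumes <- function(volumes, path) {
  write.table(
    data.frame(region = names(volumes), volume = as.numeric(volumes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_node_volumes
#' @export
read_node_volumes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  setNames(df$volume, df$region)
}

#' Write a voxel volume as NIfTI-1
#'
#' Count profiles, probability maps and masks are written as floating-point
#' NIfTI; MPM label volumes as integer-coded NIfTI with a sidecar label-map
#' table (`<path>.labels.tsv`).
#'
#' @param vol 3D array (or `mpm_volume`).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size Voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = c(1, 1, 1)) {
  is_mpm <- inherits(vol, "mpm_volume")
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr, pixdim = voxel_size)
  RNifti::writeNifti(img, path)
  if (is_mpm) {
    codes <- mpm_label_codes()
    write.table(
      data.frame(code = as.integer(codes), label = names(codes)),
      paste0(path, ".labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write a run manifest
#'
#' Records the configuration, RNG seed, package version, and the pipeline's
#' pinned methodological conventions (MPM tie rule, node-size normalization,
#' sparsity tie-break, AUC rule) next to the outputs, so every table can be
#' traced back to the exact settings that produced it.
#'
#' @param config A `synthetic_config` (or list of them) used for the run.
#' @param path Output YAML path.
#' @param extra Optional named list of additional fields.
#' @export
write_manifest <- function(config, path, extra = list()) {
  cfg_list <- function(cfg) {
    list(
      n_subjects = cfg$n_subjects,
      n_regions = cfg$n_regions,
      target_pattern_correlation =
        as.vector(cfg$target_pattern_correlation),
      subject_noise_sd = cfg$subject_noise_sd,
      grid_shape = cfg$grid_shape,
      gradient_strength = cfg$gradient_strength,
      mean_count = cfg$mean_count,
      rng_seed = cfg$rng_seed
    )
  }
  cfg_out <- if (inherits(config, "synthetic_config")) {
    cfg_list(config)
  } else {
    lapply(config, cfg_list)
  }
  manifest <- c(
    list(
      package = "mtplusconn",
      version = as.character(packageVersion("mtplusconn")),
      config = cfg_out,
      conventions = list(
        mpm_tie_rule = "exact ties at the maximum -> OVERLAP",
        mpm_zero_rule = "all-zero strengths -> UNCLASSIFIED",
        overlap_denominator = "classified voxels only",
        node_size_normalization = "w = c * 2 / (Va + Vb)",
        top_fraction_count = "ceiling, ties by label order",
        sparsity_tie_break = "weight desc, then label pair",
        sparsity_edge_count = "ceiling(s * n(n-1)/2)",
        auc_rule = "trapezoid over the sparsity sweep",
        fisher_z_clip = 1e-7
      )
    ),
    extra
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a declarative run configuration file
#'
#' Parses a YAML file whose fields mirror the arguments of
#' [synthetic_config()] into a validated configuration object.
#'
#' @param path YAML file path.
#' @return A `synthetic_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(synthetic_config)))]
  if (!is.null(args$target_pattern_correlation) &&
      length(args$target_pattern_correlation) == 9L) {
    args$target_pattern_correlation <-
      matrix(unlist(args$target_pattern_correlation), 3L, 3L)
  }
  do.call(synthetic_config, args)
}
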