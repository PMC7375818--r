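#' Configuration for a synthetic study run
#'
#' Defaults mirror the desk-scale version of the published study design:
#' 5 layers x 5 cases x 3 stacks per case, stacks of 10 x 8 x 5 um
#' (400 um^3, the order of real FIB/SEM stack volumes), layer profiles
#' calibrated to the published per-layer table, per-stack fixation-artifact
#' fractions uniform on [0, 0.2], and an unbiased counting frame inset 200 nm
#' from the stack faces. Synthetic coordinates are generated directly in
#' corrected (tissue) space, so the shrinkage factors default to identity;
#' pass measured factors when analysing real, processed-tissue tables.
#'
#' @param profiles named list of \code{\link{layer_profile}}s (default the
#'   packaged CA1 calibration).
#' @param n_cases number of cases (subjects).
#' @param stacks_per_case stacks per case and layer.
#' @param stack_extent nm extents of each stack (length 3).
#' @param artifact_range range of per-stack artifact fractions (length 2,
#'   within [0, 0.5)); artifacts carve synapse-free blobs out of the stack.
#' @param mask_voxel in-plane voxel size in nm of the (coarse) artifact-mask
#'   grid.
#' @param mask_voxel_z section thickness in nm of the artifact-mask grid
#'   (default 25, so every-20th-section sampling sees several sections even
#'   in thin stacks).
#' @param frame_margin counting-frame inset from the stack faces, nm.
#' @param factors a \code{\link{shrinkage_factors}} (identity by default).
#' @param spatial_n_sim CSR envelope simulations per tested stack (99, the
#'   conventional envelope count); set to 0 to skip the spatial stage.
#' @param spatial_stacks \code{"first"} (one stack per layer; default) or
#'   \code{"all"}.
#' @return a \code{study_config} list.
#' @export
study_config <- function(profiles = ca1_layer_profiles(),
                         n_cases = 5L, stacks_per_case = 3L,
                         stack_extent = c(10000, 8000, 5000),
                         artifact_range = c(0, 0.2),
                         mask_voxel = 100,
                         mask_voxel_z = 25,
                         frame_margin = 200,
                         factors = no_shrinkage(),
                         spatial_n_sim = 99L,
                         spatial_stacks = c("first", "all")) {
  stopifnot(inherits(factors, "shrinkage_factors"),
            all(vapply(profiles, inherits, logical(1), "layer_profile")))
  if (artifact_range[1] < 0 || artifact_range[2] >= 0.5 ||
      artifact_range[2] < artifact_range[1])
    stop("'artifact_range' must be within [0, 0.5)", call. = FALSE)
  structure(list(profiles = profiles, n_cases = as.integer(n_cases),
                 stacks_per_case = as.integer(stacks_per_case),
                 stack_extent = as.numeric(stack_extent),
                 artifact_range = as.numeric(artifact_range),
                 mask_voxel = mask_voxel, mask_voxel_z = mask_voxel_z,
                 frame_margin = frame_margin,
                 factors = factors, spatial_n_sim = as.integer(spatial_n_sim),
                 spatial_stacks = match.arg(spatial_stacks)),
            class = "study_config")
}

#' Load a study configuration from a YAML or JSON file
#'
#' Scalar fields override the defaults of \code{\link{study_config}};
#' \code{factors} may be given as a mapping with \code{p2} and \code{pz}.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a \code{study_config}.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("n_cases", "stacks_per_case", "stack_extent",
               "artifact_range", "mask_voxel", "frame_margin",
               "spatial_n_sim", "spatial_stacks"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$factors))
    args$factors <- shrinkage_factors(1, cfg$factors$p2, 1, cfg$factors$pz)
  do.call(study_config, args)
}

# mean +/- SD over case means (cases are the sampling unit)
case_mean_sd <- function(values, cases) {
  if (!length(values)) return(c(mean = NA_real_, sd = NA_real_))
  cm <- tapply(values, cases, mean)
  c(mean = mean(cm), sd = if (length(cm) > 1) sd(cm) else NA_real_)
}

#' Run the full synthetic study
#'
#' Generates the synapse populations for every layer, case and stack;
#' carves out fixation-artifact regions; filters through the unbiased
#' counting frame; estimates per-stack artifact fractions by Cavalieri point
#' counting and computes raw and corrected synaptic densities; measures
#' intersynaptic (nearest-neighbour) distances; runs CSR envelope tests on a
#' subset of stacks; and applies the statistical battery. Fully reproducible
#' from the seed.
#'
#' @param config a \code{\link{study_config}}.
#' @param seed integer seed driving all randomness of the run.
#' @param out_dir optional directory; when given, layer summaries, the
#'   synapse table, per-stack results, spatial verdicts and the statistical
#'   table are written as CSV plus a small markdown report.
#' @return an object of class \code{ca1_study}: list with \code{synapses}
#'   (included records with case/stack ids), \code{stacks} (per-stack
#'   metrics), \code{layer_summary}, \code{proportions}, \code{spatial},
#'   \code{stats} and \code{config}.
#' @export
run_study <- function(config = study_config(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  with_seed(seed, run_study_impl(config, out_dir))
}

run_study_impl <- function(config, out_dir) {
  ext <- config$stack_extent
  geom <- stack_geometry(ext[1], ext[2], ext[3])
  mask_geom <- stack_geometry(ext[1], ext[2], ext[3],
                              voxel_xy = config$mask_voxel,
                              voxel_z = config$mask_voxel_z)
  frame <- counting_frame(geom, margin = config$frame_margin)
  v_frame <- frame_volume_um3(frame)
  grid <- grid_spec(4e5)  # 400,000 nm^2 per point, the FIB/SEM convention

  stacks <- list(); synapses <- list(); spatial_rows <- list()
  stack_id <- 0L
  for (ly in names(config$profiles)) {
    prof <- config$profiles[[ly]]
    for (case in seq_len(config$n_cases)) {
      for (st in seq_len(config$stacks_per_case)) {
        stack_id <- stack_id + 1L
        a_true <- runif(1, config$artifact_range[1], config$artifact_range[2])
        pop <- generate_population(geom, prof)
        a_est <- 0
        if (a_true > 0) {
          mask <- generate_artifact_mask(mask_geom, a_true)
          pop <- thin_by_mask(pop, mask, mask_geom)
          a_est <- estimate_artifact_fraction(mask, grid, 20L,
                                              voxel_xy = config$mask_voxel)
        }
        inc <- counting_frame_filter(pop, frame)
        n_inc <- nrow(inc)
        dens_raw <- n_inc / v_frame
        dens_cor <- synaptic_density(max(n_inc, 0), v_frame,
                                     config$factors, a_est)$density
        isd <- NA_real_
        if (n_inc >= 2) {
          pat <- point_pattern(inc[, c("cx_nm", "cy_nm", "cz_nm")], geom)
          isd <- mean(nn_distances(pat))
          if ((config$spatial_stacks == "all" ||
               (case == 1L && st == 1L)) && config$spatial_n_sim > 0 &&
              n_inc >= 10) {
            for (fn in c("G", "F", "K")) {
              env <- csr_envelope(pat, fn, n_sim = config$spatial_n_sim)
              spatial_rows[[length(spatial_rows) + 1L]] <-
                data.frame(layer = ly, case = case, stack = st, fn = fn,
                           within_envelope = env$verdict,
                           stringsAsFactors = FALSE)
            }
          }
        }
        if (n_inc) {
          inc$case <- case; inc$stack <- st
          synapses[[length(synapses) + 1L]] <- inc
        }
        stacks[[length(stacks) + 1L]] <- data.frame(
          layer = ly, case = case, stack = st, n_included = n_inc,
          cf_volume_um3 = v_frame,
          artifact_true = a_true, artifact_est = a_est,
          density_raw = dens_raw, density_corrected = dens_cor,
          n_AS = sum(inc$polarity == "AS"), n_SS = sum(inc$polarity == "SS"),
          isd_nm = isd, stringsAsFactors = FALSE)
      }
    }
  }
  stacks <- do.call(rbind, stacks)
  synapses <- if (length(synapses)) do.call(rbind, synapses)
              else empty_population()
  spatial <- if (length(spatial_rows)) do.call(rbind, spatial_rows)
             else data.frame()

  layer_summary <- build_layer_summary(synapses, stacks, config)
  proportions <- proportions_report(synapses)
  stats_tbl <- study_statistics(synapses, stacks)

  study <- structure(list(synapses = synapses, stacks = stacks,
                          layer_summary = layer_summary,
                          proportions = proportions, spatial = spatial,
                          stats = stats_tbl, config = config),
                     class = "ca1_study")
  if (!is.null(out_dir)) write_study_outputs(study, out_dir)
  study
}

# remove records whose centroid falls inside the artifact mask
thin_by_mask <- function(pop, mask, mask_geom) {
  if (!nrow(pop)) return(pop)
  dims <- dim(mask)
  ix <- pmin(floor(pop$cx_nm / mask_geom$voxel_xy) + 1L, dims[1])
  iy <- pmin(floor(pop$cy_nm / mask_geom$voxel_xy) + 1L, dims[2])
  iz <- pmin(floor(pop$cz_nm / mask_geom$voxel_z) + 1L, dims[3])
  inside <- mask[cbind(ix, iy, iz)] > 0
  pop[!inside, , drop = FALSE]
}

build_layer_summary <- function(synapses, stacks, config) {
  do.call(rbind, lapply(unique(stacks$layer), function(ly) {
    s <- stacks[stacks$layer == ly, ]
    syn <- synapses[synapses$layer == ly, , drop = FALSE]
    n_as <- sum(syn$polarity == "AS"); n_ss <- sum(syn$polarity == "SS")
    n_tot <- n_as + n_ss
    v_raw <- sum(s$cf_volume_um3)
    v_cor <- sum(apply_correction(s$cf_volume_um3, "volume", config$factors,
                                  0) * (1 - s$artifact_est))
    d_all <- case_mean_sd(s$density_corrected, s$case)
    d_as <- case_mean_sd(s$density_corrected * ifelse(s$n_included > 0,
                         s$n_AS / pmax(s$n_included, 1), 0), s$case)
    d_ss <- case_mean_sd(s$density_corrected * ifelse(s$n_included > 0,
                         s$n_SS / pmax(s$n_included, 1), 0), s$case)
    isd <- case_mean_sd(s$isd_nm[!is.na(s$isd_nm)],
                        s$case[!is.na(s$isd_nm)])
    area_as <- if (n_as) mean(syn$sas_area_nm2[syn$polarity == "AS"]) else NA
    area_ss <- if (n_ss) mean(syn$sas_area_nm2[syn$polarity == "SS"]) else NA
    data.frame(layer = ly, n_AS = n_as, n_SS = n_ss, n_total = n_tot,
               pct_AS = proportion_pct(n_as, n_tot),
               pct_SS = proportion_pct(n_ss, n_tot),
               cf_volume_raw = v_raw, cf_volume_corrected = v_cor,
               density_AS_mean = d_as["mean"], density_AS_sd = d_as["sd"],
               density_SS_mean = d_ss["mean"], density_SS_sd = d_ss["sd"],
               density_all_mean = d_all["mean"], density_all_sd = d_all["sd"],
               isd_mean_nm = isd["mean"], isd_sd_nm = isd["sd"],
               sas_area_AS_mean = area_as, sas_area_SS_mean = area_ss,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Per-layer and pooled composition tables
#'
#' Percentages of polarity, of postsynaptic targets (within identifiable
#' targets only, per polarity and combined), and of shape classes, with
#' explicit denominators. Pooled rows use layer \code{"all"}. Zero
#' denominators yield NA percentages.
#'
#' @param records a synapse table.
#' @return list of data.frames: \code{polarity}, \code{targets},
#'   \code{shapes}.
#' @export
proportions_report <- function(records) {
  layers <- c(intersect(SYNAPSE_LAYERS, unique(records$layer)), "all")
  subset_layer <- function(ly)
    if (ly == "all") records else records[records$layer == ly, , drop = FALSE]

  polarity <- do.call(rbind, lapply(layers, function(ly) {
    r <- subset_layer(ly)
    n_as <- sum(r$polarity == "AS"); n_ss <- sum(r$polarity == "SS")
    data.frame(layer = ly, n_AS = n_as, n_SS = n_ss, n_total = n_as + n_ss,
               pct_AS = proportion_pct(n_as, n_as + n_ss),
               pct_SS = proportion_pct(n_ss, n_as + n_ss),
               stringsAsFactors = FALSE)
  }))

  targets <- do.call(rbind, lapply(layers, function(ly) {
    r <- subset_layer(ly)
    r <- r[r$target != "unknown", , drop = FALSE]
    do.call(rbind, lapply(c("AS", "SS", "all"), function(pol) {
      rp <- if (pol == "all") r else r[r$polarity == pol, , drop = FALSE]
      denom <- nrow(rp)
      do.call(rbind, lapply(setdiff(SYNAPSE_TARGETS, "unknown"),
                            function(tg) {
        n <- sum(rp$target == tg)
        data.frame(layer = ly, polarity = pol, target = tg, n = n,
                   denominator = denom, pct = proportion_pct(n, denom),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  shapes <- do.call(rbind, lapply(layers, function(ly) {
    r <- subset_layer(ly)
    do.call(rbind, lapply(c("AS", "SS"), function(pol) {
      rp <- r[r$polarity == pol, , drop = FALSE]
      denom <- nrow(rp)
      do.call(rbind, lapply(SYNAPSE_SHAPES, function(sh) {
        n <- sum(rp$shape_class == sh)
        data.frame(layer = ly, polarity = pol, shape_class = sh, n = n,
                   denominator = denom, pct = proportion_pct(n, denom),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))

  list(polarity = polarity, targets = targets, shapes = shapes)
}

#' Relative layer-thickness contributions
#'
#' Converts absolute layer thicknesses to percent of the total, rounded to
#' integers (the convention for reporting laminar shares).
#'
#' @param thicknesses named positive numeric vector (any common unit).
#' @return data.frame with \code{layer}, \code{thickness}, \code{share_pct}.
#' @examples
#' thickness_report(c(alveus = 0.34, SO = 0.06, SP = 1.13,
#'                    SR = 0.55, SLM = 0.62))
#' @export
thickness_report <- function(thicknesses) {
  if (any(thicknesses <= 0) || !length(thicknesses))
    stop("thicknesses must be positive", call. = FALSE)
  total <- sum(thicknesses)
  data.frame(layer = names(thicknesses) %||% seq_along(thicknesses),
             thickness = unname(thicknesses),
             share_pct = round_half_up(100 * unname(thicknesses) / total, 0),
             stringsAsFactors = FALSE)
}

# the statistical battery over a study's tables
study_statistics <- function(synapses, stacks) {
  rows <- list()
  add <- function(analysis, tr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, method = tr$method, statistic = tr$statistic,
      df = tr$df, p = tr$p, alpha = tr$alpha, n_basis = tr$n_basis,
      significant = tr$significant, stringsAsFactors = FALSE)
  }
  layers <- unique(stacks$layer)
  if (nrow(synapses) && length(layers) > 1) {
    tab <- vapply(layers, function(ly)
      c(AS = sum(synapses$layer == ly & synapses$polarity == "AS"),
        SS = sum(synapses$layer == ly & synapses$polarity == "SS")),
      numeric(2))
    if (all(colSums(tab) > 0))
      add("polarity x layer", suppressWarnings(chi2_contingency(tab)))
    groups <- lapply(layers, function(ly) {
      s <- stacks[stacks$layer == ly, ]
      tapply(s$density_corrected, s$case, mean)
    })
    names(groups) <- layers
    if (all(vapply(groups, length, integer(1)) >= 2))
      add("density across layers", anova_tukey(groups))
    as_area <- synapses$sas_area_nm2[synapses$polarity == "AS"]
    ss_area <- synapses$sas_area_nm2[synapses$polarity == "SS"]
    if (length(as_area) > 10 && length(ss_area) > 10) {
      add("SAS area AS vs SS (distribution)", ks_two_sample(as_area, ss_area))
      add("SAS area AS vs SS (location)",
          mann_whitney(as_area, ss_area, n_basis = "synapses"))
    }
    ok <- !is.na(stacks$isd_nm)
    if (sum(ok) >= 3) {
      r2 <- r_squared(stacks$density_corrected[ok], stacks$isd_nm[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "density vs intersynaptic distance", method = "R-squared",
        statistic = r2, df = NA_real_, p = NA_real_, alpha = NA_real_,
        n_basis = "stacks", significant = NA, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_synapse_csv(study$synapses, file.path(out_dir, "synapses.csv"))
  write.csv(study$stacks, file.path(out_dir, "stacks.csv"), row.names = FALSE)
  write.csv(study$layer_summary, file.path(out_dir, "layer_summary.csv"),
            row.names = FALSE)
  write.csv(study$proportions$polarity,
            file.path(out_dir, "proportions_polarity.csv"), row.names = FALSE)
  write.csv(study$proportions$targets,
            file.path(out_dir, "proportions_targets.csv"), row.names = FALSE)
  write.csv(study$proportions$shapes,
            file.path(out_dir, "proportions_shapes.csv"), row.names = FALSE)
  if (nrow(study$spatial))
    write.csv(study$spatial, file.path(out_dir, "spatial_verdicts.csv"),
              row.names = FALSE)
  if (nrow(study$stats))
    write.csv(study$stats, file.path(out_dir, "statistics.csv"),
              row.names = FALSE)
  report <- c("# Synthetic CA1 study report", "",
              sprintf("Included synapses: %d", nrow(study$synapses)),
              sprintf("Stacks: %d", nrow(study$stacks)), "",
              "## Per-layer summary", "",
              utils::capture.output(print(study$layer_summary)))
  writeLines(report, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.ca1_study <- function(x, ...) {
  cat(sprintf("synthetic CA1 study: %d synapses in %d stacks across %d layers\n",
              nrow(x$synapses), nrow(x$stacks),
              length(unique(x$stacks$layer))))
  ls <- x$layer_summary
  for (i in seq_len(nrow(ls)))
    cat(sprintf("  %-4s n=%5d  %%AS=%6.2f  density=%.2f +/- %.2f /um^3\n",
                ls$layer[i], ls$n_total[i], ls$pct_AS[i],
                ls$density_all_mean[i], ls$density_all_sd[i]))
  if (nrow(x$spatial))
    cat(sprintf("  spatial CSR verdicts within envelope: %d / %d\n",
                sum(x$spatial$within_envelope), nrow(x$spatial)))
  invisible(x)
}
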