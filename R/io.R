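## Readers/writers, run configuration and the staged analysis pipeline.

#' Read a delimited angle table into ensembles
#'
#' Expects a delimited text file with an `angle_deg` column and an optional
#' `device_label` column (single unlabeled device otherwise).  Rows whose
#' angle falls outside (0, 180) degrees or cannot be parsed are rejected and
#' counted; rejections are reported in the `rejected` attribute together
#' with their row numbers, and rejecting more than `max_reject_frac` of the
#' rows is an error.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @param angle_col,label_col column names.
#' @param max_reject_frac maximum tolerated rejected fraction (default 0.5).
#' @return Named list of [angle_ensemble()] objects (one per label), with
#'   attribute `rejected` (a list with `count` and `rows`).
#' @export
read_angle_table <- function(path, sep = ",", angle_col = "angle_deg",
                             label_col = "device_label",
                             max_reject_frac = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty angle table: ", path, call. = FALSE)
  if (!angle_col %in% names(df))
    stop(sprintf("missing required column `%s` in %s", angle_col, path),
         call. = FALSE)
  ang <- suppressWarnings(as.numeric(df[[angle_col]]))
  bad <- !is.finite(ang) | ang <= 0 | ang >= 180
  if (mean(bad) > max_reject_frac)
    stop(sprintf("%d of %d rows rejected (unparseable or outside (0, 180)); first bad rows: %s",
                 sum(bad), nrow(df),
                 paste(utils::head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  labels <- if (label_col %in% names(df)) as.character(df[[label_col]])
            else rep("device", nrow(df))
  keep <- !bad
  out <- lapply(split(ang[keep], labels[keep]), function(a)
    suppressWarnings(angle_ensemble(a, source = "measured")))
  for (lb in names(out)) out[[lb]]$device_label <- lb
  attr(out, "rejected") <- list(count = sum(bad), rows = which(bad))
  out
}

#' Run configuration
#'
#' Collects every tunable of the pipeline in one list with the stated
#' defaults: thermal energy 4.114 pN nm, 61-nm arms with tip attachment,
#' 11--61 nm radial force range, 5-degree angle bins, density cutoff 0.001,
#' 50 bootstrap replicates, coupling-grid spacing 2 nm, sample Lc = 85 nm
#' and lp = 50 nm, linker Gaussian chains n = 4, b = 1.5 nm, and the
#' nucleosome defaults of [nucleosome_spec()].
#'
#' @param ... overrides of any default field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    kBT = 4.114,
    arm_length = 61, attachment_radius = 61,
    d_min = 11, d_max = 61,
    angle_bin = 5, density_cutoff = 0.001, spar = NULL,
    bootstrap_replicates = 50L, seed = 1L,
    grid_spacing = 2,
    sample_Lc = 85, sample_lp = 50,
    linker_n = 4, linker_b = 1.5,
    nucleosome = list(),
    elastica_end_to_end = 49)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  for (nm in c("kBT", "arm_length", "attachment_radius", "d_min", "d_max",
               "angle_bin", "grid_spacing", "sample_Lc", "sample_lp",
               "linker_n", "linker_b"))
    stop_if_not_positive(cfg[[nm]], nm)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path file path; format decided by extension (`.json` vs anything
#'   else, parsed as YAML).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  run_config(raw)
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical JSON serialization, stamped into every
#' pipeline output so reruns can be matched to their configuration.
#'
#' @param config a [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stages on a set of angle ensembles:
#'
#' * `landscape` -- density, Boltzmann free energy, torque, force map and
#'   bootstrap peak-angle uncertainty per ensemble; always required.
#' * `couple` -- coupled hinge+sample prediction and force report for each
#'   ensemble's distribution.
#' * `nucleosome` -- unwrapping and constrained-angle predictions per
#'   ensemble.
#' * `elastica` -- post-buckling force of the configured sample.
#'
#' When `out_dir` is given, each stage writes CSV tables and a JSON summary
#' stamped with the configuration hash and seed.
#'
#' @param ensembles named list of [angle_ensemble()] objects (e.g. from
#'   [read_angle_table()]), or a single ensemble.
#' @param config a [run_config()].
#' @param stages character subset of
#'   `c("landscape", "couple", "nucleosome", "elastica")`.
#' @param out_dir optional output directory.
#' @return A list of per-stage results, invisibly when writing to disk.
#' @export
run_pipeline <- function(ensembles, config = run_config(),
                         stages = c("landscape", "couple", "nucleosome",
                                    "elastica"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (inherits(ensembles, "angle_ensemble"))
    ensembles <- stats::setNames(list(ensembles), ensembles$device_label)
  if (!"landscape" %in% stages && any(c("couple", "nucleosome") %in% stages))
    stop("stages `couple` and `nucleosome` require the `landscape` stage",
         call. = FALSE)
  thermal <- thermal_scale(config$kBT)
  geometry <- hinge_geometry(config$arm_length, config$attachment_radius)
  hash <- config_hash(config)
  res <- list(config = config, config_hash = hash)

  if ("landscape" %in% stages) {
    res$landscape <- lapply(ensembles, function(ens) {
      dist <- estimate_density(ens, config$angle_bin)
      fel <- boltzmann_free_energy(dist, config$density_cutoff, config$spar)
      tq <- torque_profile(fel, thermal)
      fm <- force_map(tq, config$d_min, config$d_max)
      boot <- bootstrap_uncertainty(
        ens,
        function(a) peak_angle(estimate_density(
          angle_ensemble(a, ens$device_label, ens$source), config$angle_bin)),
        replicates = config$bootstrap_replicates, seed = config$seed)
      list(distribution = dist, landscape = fel, torque = tq,
           force_map = fm, peak_bootstrap = boot)
    })
  }
  if ("couple" %in% stages) {
    sample_wlc <- wlc(config$sample_Lc, config$sample_lp)
    linker <- gaussian_chain(config$linker_n, config$linker_b)
    res$couple <- lapply(res$landscape, function(st) {
      spec <- coupled_system(st$distribution, linker, linker, sample_wlc,
                             geometry, config$grid_spacing)
      pred <- predict_coupled_angle_distribution(spec)
      prof <- coupled_free_energy_and_force(spec, thermal,
                                            distribution = pred)
      list(spec = spec, distribution = pred, profile = prof)
    })
  }
  if ("nucleosome" %in% stages) {
    nspec <- do.call(nucleosome_spec, config$nucleosome)
    res$nucleosome <- lapply(res$landscape, function(st) {
      uw <- predict_unwrap_distribution(st$distribution, nspec, geometry)
      ca <- predict_constrained_angle_distribution(st$distribution, nspec,
                                                   geometry)
      theta_star <- peak_angle(ca)
      force <- tryCatch(
        tensile_force_estimate(st$landscape, theta_star, geometry, thermal),
        error = function(e) NA_real_)
      list(unwrapping = uw, constrained = ca, theta_star = theta_star,
           tensile_force_pN = as.numeric(force))
    })
  }
  if ("elastica" %in% stages) {
    spec <- elastica_spec(config$sample_Lc, lp = config$sample_lp,
                          thermal = thermal)
    res$elastica <- list(
      spec = spec,
      critical_force_pN = euler_critical_force(spec),
      end_to_end = config$elastica_end_to_end,
      force_pN = postbuckling_force(config$elastica_end_to_end, spec))
  }
  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, out_dir)
    return(invisible(res))
  }
  res
}

## CSV + JSON emission for run_pipeline; one file set per stage.
write_pipeline_outputs <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stamp <- list(config_hash = res$config_hash, seed = res$config$seed)
  summary <- list(stamp = stamp)
  for (lb in names(res$landscape)) {
    st <- res$landscape[[lb]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", lb)
    write.csv(data.frame(theta_deg = st$landscape$theta,
                         G_kBT = st$landscape$G),
              file.path(out_dir, paste0(safe, "_landscape.csv")),
              row.names = FALSE)
    write.csv(data.frame(theta_deg = st$torque$theta,
                         torque_pN_nm = st$torque$torque),
              file.path(out_dir, paste0(safe, "_torque.csv")),
              row.names = FALSE)
    summary$devices[[lb]] <- list(
      n = st$distribution$n,
      valid_range_deg = st$landscape$valid_range,
      peak_angle_deg = st$peak_bootstrap$point_estimate,
      peak_angle_sd_deg = st$peak_bootstrap$sd)
  }
  for (lb in names(res$couple)) {
    cp <- res$couple[[lb]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", lb)
    write.csv(data.frame(theta_deg = cp$profile$theta,
                         G_pN_nm = cp$profile$G,
                         force_pN = cp$profile$force),
              file.path(out_dir, paste0(safe, "_coupled.csv")),
              row.names = FALSE)
  }
  for (lb in names(res$nucleosome)) {
    nc <- res$nucleosome[[lb]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", lb)
    write.csv(data.frame(unwrapped_bp_mid = nc$unwrapping$mids,
                         density_per_bp = nc$unwrapping$density),
              file.path(out_dir, paste0(safe, "_unwrapping.csv")),
              row.names = FALSE)
    summary$nucleosome[[lb]] <- list(
      mean_unwrapped_bp = mean_unwrapped(nc$unwrapping),
      theta_star_deg = nc$theta_star,
      tensile_force_pN = nc$tensile_force_pN)
  }
  if (!is.null(res$elastica))
    summary$elastica <- res$elastica[c("critical_force_pN", "end_to_end",
                                       "force_pN")]
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
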