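#' Write a trial record to CSV (plus a JSON sidecar)
#'
#' One row per step with the documented column schema (`step`, positions,
#' link distances, `offset`, contact flags, `o1..o8` per agent, click
#' events). The realized configuration, initial conditions and seed go into
#' a `.json` sidecar next to the CSV so the trial is reproducible from its
#' files alone.
#'
#' @param record a [run_trial()] record.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(record, path) {
  write.csv(record$series, path, row.names = FALSE)
  side <- sidecar_path(path)
  cfg <- record$config
  cfg$seed <- NULL
  jsonlite::write_json(list(config = unclass(cfg), init = record$init,
                            seed = record$seed),
                       side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path),
                                      ".json")

#' Read a trial record back from CSV
#'
#' Restores the series and, when the JSON sidecar is present, the
#' configuration, initial conditions and seed. Analysis functions are pure
#' functions of the record, so a re-read record analyzes identically.
#'
#' @param path CSV path written by [write_trial_csv()].
#' @return A `trial_record`.
#' @export
read_trial_csv <- function(path) {
  series <- read.csv(path)
  config <- NULL; init <- NULL; seed <- NULL
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    cfg <- meta$config
    config <- trial_config(steps = cfg$steps, h = cfg$h,
                           rf1_base = cfg$rf1_base, rf2_0 = cfg$rf2_0,
                           d1_base = cfg$d1_base, d2_0 = cfg$d2_0,
                           perturb_rf1 = cfg$perturb_rf1,
                           perturb_d1 = cfg$perturb_d1,
                           perturb_range = cfg$perturb_range,
                           noise_sd = cfg$noise_sd,
                           threshold = cfg$threshold,
                           contact_radius = cfg$contact_radius,
                           seed = meta$seed)
    init <- meta$init
    seed <- meta$seed
  } else {
    # minimal config so windowed analyses know the step size
    config <- trial_config(steps = nrow(series))
    init <- list(rf1_0 = series$rf1[1L], rf2_0 = series$rf2[1L],
                 d1_0 = series$d1[1L], d2_0 = series$d2[1L])
  }
  structure(list(series = series, config = config, seed = seed,
                 init = init),
            class = "trial_record")
}

#' Write / read a genotype as JSON
#'
#' @param geno a [genotype()].
#' @param path JSON path.
#' @return `write_genotype_json()`: `path` invisibly;
#'   `read_genotype_json()`: a validated `genotype` (a malformed file errors
#'   naming the offending gene index).
#' @export
write_genotype_json <- function(geno, path) {
  geno <- genotype(geno)
  jsonlite::write_json(list(genes = as.numeric(geno)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genotype_json
#' @export
read_genotype_json <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$genes)) stop("genotype file has no 'genes' field")
  genotype(obj$genes)
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run directory: package version,
#' the fully resolved configuration, the master seed and any derived
#' sub-seeds, and an MD5-checksummed file inventory.
#'
#' @param config resolved configuration (any JSON-serializable list).
#' @param seed master seed.
#' @param files character vector of artifact file paths.
#' @param sub_seeds named derived seeds (optional).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, files = character(0),
                         sub_seeds = NULL) {
  inv <- if (length(files) > 0) {
    data.frame(file = basename(files),
               md5 = unname(tools::md5sum(files)),
               stringsAsFactors = FALSE)
  } else data.frame(file = character(0), md5 = character(0))
  structure(list(tool = "dyadmimicry",
                 version = as.character(utils::packageVersion("dyadmimicry")),
                 config = config, seed = seed, sub_seeds = sub_seeds,
                 files = inv),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
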