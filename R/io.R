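# CSV and JSON readers/writers. All numeric columns are written with 17
# significant digits so every file round-trips bit-exactly through its
# reader; units are embedded in the column names to prevent unit drift.

fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g"),
    character(1))
  out
}

write_table_exact <- function(df, path, num_cols) {
  out <- df
  for (cl in num_cols) out[[cl]] <- fmt_num(df[[cl]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write diameter-profile CSV files
#'
#' Column layout `arclength_nm,diameter_nm,flag`; numeric fields are written
#' to full precision and round-trip bit-exactly.
#'
#' @param profile A [diameter_profile()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   a [diameter_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "diameter_profile"))
  write_table_exact(profile, path, c("arclength_nm", "diameter_nm"))
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("arclength_nm", "diameter_nm", "flag")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns ", paste(need, collapse = ","))
  diameter_profile(as.numeric(df$arclength_nm), as.numeric(df$diameter_nm),
                   df$flag)
}

#' Read and write centerline polyline CSV files
#'
#' Column layout `x_px,y_px`, one row per vertex, distal tip first.
#'
#' @param p A [polyline()].
#' @param path File path.
#' @return `write_polyline_csv` returns `path` invisibly; `read_polyline_csv`
#'   a [polyline()].
#' @export
write_polyline_csv <- function(p, path) {
  stopifnot(inherits(p, "polyline"))
  write_table_exact(as.data.frame(p), path, c("x_px", "y_px"))
}

#' @rdname write_polyline_csv
#' @export
read_polyline_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_px", "y_px") %in% names(df)))
    stop("polyline CSV must have columns x_px,y_px")
  if (nrow(df) < 2)
    stop("polyline CSV must contain at least 2 points")
  polyline(as.numeric(df$x_px), as.numeric(df$y_px))
}

#' Read and write kinetics CSV files
#'
#' Column layout `cilium_id,time_min,length_nm` with an optional `kind`
#' column (`tip` or `full`).
#'
#' @param data A [kinetics_dataset()].
#' @param path File path.
#' @param kind Dataset kind used when the file has no `kind` column.
#' @return `write_kinetics_csv` returns `path` invisibly;
#'   `read_kinetics_csv` a [kinetics_dataset()].
#' @export
write_kinetics_csv <- function(data, path) {
  stopifnot(inherits(data, "kinetics_dataset"))
  df <- as.data.frame(data)
  df$kind <- attr(data, "kind")
  write_table_exact(df, path, c("time_min", "length_nm"))
}

#' @rdname write_kinetics_csv
#' @export
read_kinetics_csv <- function(path, kind = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("kinetics CSV is empty")
  need <- c("cilium_id", "time_min", "length_nm")
  if (!all(need %in% names(df)))
    stop("kinetics CSV must have columns ", paste(need, collapse = ","))
  df$time_min <- as.numeric(df$time_min)
  df$length_nm <- as.numeric(df$length_nm)
  if (is.null(kind)) {
    kind <- if ("kind" %in% names(df)) unique(df$kind)[1] else "tip"
  }
  kinetics_dataset(df[need], kind = kind)
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the measurement pipeline. Unknown
#' fields are rejected so silent typos cannot change an analysis.
#'
#' @param pixel_size nm per pixel of the input micrographs.
#' @param bandpass List with `small_px`, `large_px` (see
#'   [bandpass_filter()]).
#' @param profile List with `step` and `half_window`, nm (see
#'   [measure_widths()]).
#' @param tip List with `degree`, `half_angle_deg`, `policy` (see
#'   [tip_length()]).
#' @param kinetics List with `model` (`"rational"` or `"balance_point"`) and
#'   `fit_means`.
#' @param seed Integer seed for simulation commands.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = NULL,
                            bandpass = list(small_px = 3, large_px = 40),
                            profile = list(step = 25, half_window = 400),
                            tip = list(degree = 6, half_angle_deg = 1.5,
                                       policy = "last_sustained"),
                            kinetics = list(model = "rational",
                                            fit_means = FALSE),
                            seed = 1L) {
  cfg <- list(pixel_size = pixel_size, bandpass = bandpass,
              profile = profile, tip = tip, kinetics = kinetics, seed = seed)
  check_fields <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown config field(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  check_fields(bandpass, c("small_px", "large_px"), "bandpass")
  check_fields(profile, c("step", "half_window"), "profile")
  check_fields(tip, c("degree", "half_angle_deg", "policy"), "tip")
  check_fields(kinetics, c("model", "fit_means"), "kinetics")
  nums <- c(pixel_size, bandpass$small_px, bandpass$large_px, profile$step,
            profile$half_window, tip$degree, tip$half_angle_deg)
  if (any(!is.na(nums) & nums <= 0))
    stop("all numeric config fields must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; fields as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  defaults <- formals(pipeline_config)
  args <- lapply(known, function(k) {
    if (k %in% names(raw)) {
      v <- raw[[k]]
      if (is.list(eval(defaults[[k]])) || k %in%
          c("bandpass", "profile", "tip", "kinetics")) as.list(v) else v
    } else NULL
  })
  names(args) <- known
  args <- args[!vapply(args, is.null, logical(1))]
  # merge partial sub-lists over defaults
  full <- formals(pipeline_config)
  for (k in c("bandpass", "profile", "tip", "kinetics")) {
    if (k %in% names(args))
      args[[k]] <- modifyList(eval(full[[k]]), args[[k]])
  }
  do.call(pipeline_config, args)
}

#' Write a tip measurement as JSON
#'
#' Layout: `cilium_id`, `tip_length_nm`, `status`, `candidates_nm` (array),
#' `cutoff`, `degree`, `rms_residual_nm`.
#'
#' @param tm A [tip_length()] result.
#' @param path Output path.
#' @param cilium_id Identifier recorded in the file.
#' @return `path`, invisibly.
#' @export
write_tip_json <- function(tm, path, cilium_id = "cilium") {
  stopifnot(inherits(tm, "tip_measurement"))
  obj <- list(cilium_id = cilium_id,
              tip_length_nm = tm$tip_length_nm,
              status = tm$status,
              candidates_nm = as.list(tm$candidates_nm),
              cutoff = tm$cutoff,
              degree = tm$fit$degree,
              rms_residual_nm = tm$fit$rms_residual)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
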