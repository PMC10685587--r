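# TSV readers/writers.  All tables are tab-separated with '#'-prefixed
# metadata header lines ("# key: value"), decimal points and no thousands
# separators, so that round trips are lossless and files diff cleanly.

.write_tsv <- function(df, path, meta = list()) {
  con <- tryCatch(file(path, open = "wt"), error = function(e) {
    lam_abort("cannot open '%s' for writing: %s", path, conditionMessage(e),
              class = "lamellar_io_error")
  })
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_meta <- function(path) {
  lines <- readLines(path, n = 200L)
  lines <- lines[startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^#\\s*([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (x in m) if (length(x) == 3L) out[[trimws(x[2])]] <- trimws(x[3])
  out
}

#' Read a Bragg-peak table
#'
#' Reads a TSV peak table with columns `order`, `two_theta`, `intensity`,
#' `intensity_err`, `phase_label` and groups the rows into one
#' [lamellar_dataset()] per lamellar phase.  Rows with non-positive intensity
#' are rejected with a logged warning rather than aborting the run, since
#' experimental peak tables routinely carry sentinel rows.
#'
#' @param path path to the TSV file
#' @param condition the [diffraction_condition()] the table was measured at
#' @return named list of `lamellar_dataset`, one per phase label
#' @export
read_peak_table <- function(path, condition) {
  if (!file.exists(path)) {
    lam_abort("peak table '%s' does not exist", path, class = "lamellar_io_error")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("order", "two_theta", "intensity", "intensity_err", "phase_label")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    lam_abort("peak table '%s' is missing column(s): %s", path,
              paste(miss, collapse = ", "), class = "lamellar_format_error")
  }
  bad <- !is.finite(df$intensity) | df$intensity <= 0
  if (any(bad)) {
    lam_log("warning", "datamodel_io",
            "rejected %d row(s) with non-positive intensity in '%s'",
            sum(bad), path)
    df <- df[!bad, , drop = FALSE]
  }
  if (anyDuplicated(df[c("phase_label", "order")])) {
    lam_abort("duplicate (phase_label, order) pair in '%s'", path)
  }
  split_df <- split(df, df$phase_label)
  out <- lapply(names(split_df), function(ph) {
    lamellar_dataset(split_df[[ph]][c("order", "two_theta", "intensity",
                                      "intensity_err")],
                     condition, phase_label = ph)
  })
  names(out) <- names(split_df)
  lam_log("info", "datamodel_io", "read %d peak(s) in %d phase group(s) from '%s'",
          nrow(df), length(out), path)
  out
}

#' Write a Bragg-peak table
#'
#' @param peaks data frame with the peak-table columns (including
#'   `phase_label`), or a single [lamellar_dataset()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_peak_table <- function(peaks, path) {
  if (inherits(peaks, "lamellar_dataset")) {
    df <- peaks$peaks
    df$phase_label <- peaks$phase_label
    peaks <- df
  }
  .write_tsv(peaks, path, meta = list(
    type = "peak_table", units = "two_theta: degree; intensity: counts"))
}

#' Write an NSLD or density profile as TSV
#'
#' The z grid and all value columns are written to full precision together
#' with '#' metadata headers, so that a read-back reproduces the object.
#'
#' @param profile an `nsld_profile` or `density_profile_set`
#' @param path output path
#' @return the path, invisibly
#' @export
write_profile_table <- function(profile, path) {
  if (inherits(profile, "nsld_profile")) {
    df <- data.frame(z_angstrom = profile$z, rho_rel = profile$rho)
    meta <- list(type = "nsld_profile", d_angstrom = format(profile$d, digits = 17),
                 n_orders_used = profile$n_orders_used,
                 signs = paste(profile$signs, collapse = ","),
                 units = "z: Angstrom; rho: relative SLD")
  } else if (inherits(profile, "density_profile_set")) {
    df <- data.frame(z_angstrom = profile$z)
    for (nm in names(profile$mass)) df[[paste0("mass_", nm)]] <- profile$mass[[nm]]
    for (nm in names(profile$charge)) df[[paste0("charge_", nm)]] <- profile$charge[[nm]]
    meta <- list(type = "density_profile_set", centering = profile$centering,
                 d_angstrom = format(profile$d, digits = 17),
                 area_per_lipid_A2 = format(profile$area_per_lipid, digits = 17),
                 temperature_K = format(profile$temperature, digits = 17),
                 units = "z: Angstrom; mass: kg/m3; charge: e/A3")
  } else {
    lam_abort("write_profile_table: unsupported object of class %s",
              paste(class(profile), collapse = "/"))
  }
  if (nrow(df) == 0L) lam_abort("refusing to write an empty profile")
  if (any(diff(df$z_angstrom) <= 0)) lam_abort("profile z grid must be strictly increasing")
  vals <- as.matrix(df[-1])
  if (anyNA(vals) || any(!is.finite(vals))) {
    idx <- which(!is.finite(vals))[1]
    lam_abort("profile contains a non-finite value (first at flat index %d)", idx)
  }
  .write_tsv(df, path, meta = meta)
}

#' Read back a profile written by [write_profile_table()]
#'
#' @param path path to the TSV file
#' @return an `nsld_profile` or `density_profile_set`, according to the
#'   file's metadata
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) {
    lam_abort("profile table '%s' does not exist", path, class = "lamellar_io_error")
  }
  meta <- .read_meta(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (identical(meta$type, "nsld_profile")) {
    new_nsld_profile(z = df$z_angstrom, rho = df$rho_rel,
                     d = as.numeric(meta$d_angstrom),
                     n_orders_used = as.integer(meta$n_orders_used),
                     signs = as.integer(strsplit(meta$signs, ",")[[1]]))
  } else if (identical(meta$type, "density_profile_set")) {
    mass <- df[grep("^mass_", names(df))]
    names(mass) <- sub("^mass_", "", names(mass))
    charge <- df[grep("^charge_", names(df))]
    names(charge) <- sub("^charge_", "", names(charge))
    density_profile_set(z = df$z_angstrom, mass = mass, charge = charge,
                        centering = meta$centering,
                        area_per_lipid = as.numeric(meta$area_per_lipid_A2),
                        temperature = as.numeric(meta$temperature_K),
                        d = as.numeric(meta$d_angstrom))
  } else {
    lam_abort("'%s' has unknown profile type '%s'", path, meta$type %||% "<none>",
              class = "lamellar_format_error")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a structure-factor set as TSV
#' @param fset a `structure_factor_set`
#' @param path output path
#' @return the path, invisibly
#' @export
write_factor_table <- function(fset, path) {
  stopifnot(inherits(fset, "structure_factor_set"))
  df <- data.frame(order = fset$orders, f = fset$f, f_err = fset$f_err,
                   sign = fset$signs)
  .write_tsv(df, path, meta = list(
    type = "structure_factors", d_angstrom = format(fset$d, digits = 17),
    d_err_angstrom = format(fset$d_err, digits = 17),
    phase_label = fset$phase_label,
    temperature_K = format(fset$condition$temperature, digits = 17),
    d2o_fraction = format(fset$condition$d2o_fraction, digits = 17)))
}

#' Read a structure-factor set written by [write_factor_table()]
#' @param path path to the TSV file
#' @param condition optional [diffraction_condition()]; reconstructed from
#'   the file metadata when omitted
#' @return a `structure_factor_set`
#' @export
read_factor_table <- function(path, condition = NULL) {
  meta <- .read_meta(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(condition)) {
    condition <- diffraction_condition(
      temperature = as.numeric(meta$temperature_K %||% "323.15"),
      d2o_fraction = as.numeric(meta$d2o_fraction %||% "0.08"))
  }
  new_structure_factor_set(
    orders = as.integer(df$order), f = df$f, f_err = df$f_err,
    signs = as.integer(df$sign), d = as.numeric(meta$d_angstrom),
    d_err = as.numeric(meta$d_err_angstrom %||% "0"),
    condition = condition, phase_label = meta$phase_label %||% "unassigned")
}
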