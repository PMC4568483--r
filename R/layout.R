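#' Plate layouts
#'
#' A plate layout maps each well of an `n_rows` x `n_cols` multiwell plate
#' (default 96-well, 8 x 12) to a compound, a concentration in micromolar,
#' an assay role and a replicate index. It is the single source of truth for
#' which wells are analyzed, which are solvent-only vehicle controls, and how
#' treatment wells group into dose series.
#'
#' Roles are `treatment`, `vehicle`, `positive_control`, `negative_control`
#' and `empty` (parsed case-insensitively). Vehicle wells must have
#' concentration 0; empty wells must have no compound. An optional `solvent`
#' column assigns each well to a vehicle group (e.g. `"DMSO"` vs `"PBS"`) so
#' that normalization can use solvent-matched controls; when absent all wells
#' share one group.
#'
#' @param wells A data frame with columns `well` (e.g. `"A1"`), `compound`,
#'   `concentration_uM`, `role`, `replicate`, and optionally `solvent`.
#' @param n_rows,n_cols Plate dimensions (rows x columns).
#'
#' @return A tibble of class `plate_layout` with one row per well and columns
#'   `well`, `row`, `col` (0-based indices), `compound`, `concentration_uM`,
#'   `role`, `replicate`, `solvent`; plate dimensions are kept in attributes
#'   `n_rows` / `n_cols`.
#' @examples
#' plate_layout(data.frame(
#'   well = c("A1", "A2"), compound = c("SDS", NA),
#'   concentration_uM = c(625, 0), role = c("treatment", "vehicle"),
#'   replicate = c(1, 1)
#' ))
#' @export
plate_layout <- function(wells, n_rows = 8, n_cols = 12) {
  if (!is_count(n_rows) || !is_count(n_cols)) {
    stop_spheroscreen("n_rows and n_cols must be positive integers",
                      "spheroscreen_validation_error")
  }
  wells <- as_tibble(wells)
  required <- c("well", "compound", "concentration_uM", "role", "replicate")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0) {
    stop_spheroscreen(
      sprintf("layout is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "spheroscreen_layout_error"
    )
  }
  if (!"solvent" %in% names(wells)) wells$solvent <- ""
  wells$solvent <- ifelse(is.na(wells$solvent), "", as.character(wells$solvent))

  if (anyDuplicated(wells$well)) {
    dup <- unique(wells$well[duplicated(wells$well)])
    stop_spheroscreen(sprintf("duplicate well name(s): %s", paste(dup, collapse = ", ")),
                      "spheroscreen_layout_error")
  }
  idx <- parse_well_name(wells$well)
  if (any(idx$row >= n_rows | idx$col >= n_cols)) {
    off <- wells$well[idx$row >= n_rows | idx$col >= n_cols]
    stop_spheroscreen(
      sprintf("well(s) outside the %dx%d grid: %s", n_rows, n_cols,
              paste(off, collapse = ", ")),
      "spheroscreen_layout_error"
    )
  }

  roles <- c("treatment", "vehicle", "positive_control", "negative_control", "empty")
  role <- tolower(trimws(as.character(wells$role)))
  if (any(!role %in% roles)) {
    stop_spheroscreen(
      sprintf("unknown role(s): %s", paste(unique(wells$role[!role %in% roles]), collapse = ", ")),
      "spheroscreen_validation_error"
    )
  }

  conc <- as.numeric(wells$concentration_uM)
  conc[role == "empty" & is.na(conc)] <- 0
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_spheroscreen("concentration_uM must be finite and >= 0",
                      "spheroscreen_validation_error")
  }
  if (any(role == "vehicle" & conc != 0)) {
    stop_spheroscreen("vehicle wells must have concentration 0",
                      "spheroscreen_validation_error")
  }
  compound <- as.character(wells$compound)
  compound[!is.na(compound) & compound == ""] <- NA_character_
  if (any(role == "empty" & !is.na(compound))) {
    stop_spheroscreen("empty wells must have no compound",
                      "spheroscreen_validation_error")
  }

  out <- tibble(
    well = as.character(wells$well),
    row = idx$row,
    col = idx$col,
    compound = compound,
    concentration_uM = conc,
    role = role,
    replicate = as.integer(wells$replicate),
    solvent = wells$solvent
  )
  out <- dplyr::arrange(out, .data$row, .data$col)
  structure(out,
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            class = c("plate_layout", class(tibble())))
}

#' Read or write a plate layout CSV
#'
#' The layout file is a CSV with header
#' `well,compound,concentration_uM,role,replicate` (plus optional `solvent`).
#' `write_plate_layout()` and `read_plate_layout()` round-trip exactly.
#'
#' @param path Path to the layout CSV.
#' @param n_rows,n_cols Plate dimensions used for validation.
#' @return A validated [plate_layout].
#' @export
read_plate_layout <- function(path, n_rows = 8, n_cols = 12) {
  if (!file.exists(path)) {
    stop_spheroscreen(sprintf("layout file not found: %s", path), "spheroscreen_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    compound = readr::col_character(),
    concentration_uM = readr::col_double(),
    role = readr::col_character(),
    replicate = readr::col_integer(),
    .default = readr::col_character()
  ))
  plate_layout(raw, n_rows = n_rows, n_cols = n_cols)
}

#' @rdname read_plate_layout
#' @param layout A [plate_layout].
#' @export
write_plate_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  readr::write_csv(
    dplyr::select(as_tibble(layout), "well", "compound", "concentration_uM",
                  "role", "replicate", "solvent"),
    path
  )
  invisible(path)
}

#' Default 96-well toxicity screen layout
#'
#' Builds the panel used throughout the package's synthetic experiments:
#' seven compounds on one 96-well plate, each with four half-log-spaced doses
#' bracketing its expected potency, in triplicate (rows A-G, one compound per
#' row). Row H holds six PBS vehicle wells, three DMSO vehicle wells, and
#' three positive-control wells (SDS at 625 uM, the detergent concentration
#' conventionally used to define full inhibition of contraction).
#' Penicillin-G serves as the flat negative control, with doses up to the
#' millimolar range.
#'
#' @param compounds A tibble describing the panel, as produced by
#'   [screen_compounds()]; its `dose_uM` list-column gives each compound's
#'   dose series.
#' @return A [plate_layout] with 96 wells.
#' @export
default_screen_layout <- function(compounds = screen_compounds()) {
  stopifnot(nrow(compounds) <= 8 - 1)
  rows <- purrr::map_dfr(seq_len(nrow(compounds)), function(i) {
    doses <- compounds$dose_uM[[i]]
    stopifnot(length(doses) == 4)
    tibble(
      well = well_name(rep(i - 1L, 12L), 0:11),
      compound = compounds$compound[i],
      concentration_uM = rep(doses, each = 3),
      role = "treatment",
      replicate = rep(1:3, times = 4),
      solvent = compounds$solvent[i]
    )
  })
  controls <- tibble(
    well = well_name(rep(7L, 12L), 0:11),
    compound = c(rep(NA_character_, 9), rep("SDS", 3)),
    concentration_uM = c(rep(0, 9), rep(625, 3)),
    role = c(rep("vehicle", 9), rep("positive_control", 3)),
    replicate = c(1:6, 1:3, 1:3),
    solvent = c(rep("PBS", 6), rep("DMSO", 3), rep("PBS", 3))
  )
  plate_layout(dplyr::bind_rows(rows, controls))
}

#' Reference compound panel for synthetic screens
#'
#' Seven compounds spanning retinoid, glucocorticoid, anthracycline,
#' antimetabolite and adenylyl-cyclase pharmacology plus detergent positive
#' and antibiotic negative controls, with nominal spheroid-assay IC50s used
#' as simulation ground truth. `flat = TRUE` marks the negative control,
#' simulated with no dose effect. Dose series are four half-log steps
#' spanning 1.5 decades around the nominal IC50 (a bracketing confirmation
#' design); the flat compound is dosed up to 5.98 mM.
#'
#' @return A tibble with columns `compound`, `ic50_uM` (NA for the flat
#'   compound), `solvent`, `flat`, and list-column `dose_uM`.
#' @export
screen_compounds <- function() {
  panel <- tibble(
    compound = c("ATRA", "dexamethasone", "doxorubicin", "5-fluorouracil",
                 "forskolin", "SDS", "penicillin-G"),
    ic50_uM = c(82.8, 84.6, 46.7, 253, 4.7, 281.8, NA),
    solvent = c("DMSO", "DMSO", "PBS", "PBS", "PBS", "PBS", "PBS"),
    flat = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  panel$dose_uM <- purrr::map2(panel$ic50_uM, panel$flat, function(ic50, flat) {
    if (flat) {
      signif(5980 * 10^c(-2, -4 / 3, -2 / 3, 0), 3)
    } else {
      signif(ic50 * 10^c(-0.75, -0.25, 0.25, 0.75), 3)
    }
  })
  panel
}
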