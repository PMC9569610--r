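#' RT-qPCR gating configuration
#'
#' Numeric gates used to call a well "amplified" and an assay "valid":
#' * `max_cq` — quantification-cycle ceiling; wells with later (or absent)
#'   Cq are non-amplifying. Default 40 cycles, the conventional end of run.
#' * `tm_tolerance` — allowed deviation of the product melt temperature from
#'   the assay's expected Tm (degrees C); off-Tm products are non-specific.
#' * `efficiency_bounds` — percent interval within which the dilution-series
#'   amplification efficiency validates an assay (default 90-110%).
#' * `expected_tm` — named numeric vector, assay id -> expected Tm.
#'
#' @param max_cq cycles, default 40.
#' @param tm_tolerance degrees C, default 1.0.
#' @param efficiency_bounds length-2 numeric, default `c(90, 110)`.
#' @param expected_tm named numeric vector (may be empty).
#' @return Object of class `qpcr_config`.
#' @export
qpcr_config <- function(max_cq = 40, tm_tolerance = 1.0,
                        efficiency_bounds = c(90, 110),
                        expected_tm = numeric()) {
  if (tm_tolerance <= 0) abort("tm_tolerance must be positive")
  if (length(efficiency_bounds) != 2 ||
      efficiency_bounds[1] >= efficiency_bounds[2]) {
    abort("efficiency_bounds must be an ordered interval")
  }
  structure(
    list(max_cq = max_cq, tm_tolerance = tm_tolerance,
         efficiency_bounds = efficiency_bounds, expected_tm = expected_tm),
    class = "qpcr_config"
  )
}

#' Amplification efficiency from a dilution series
#'
#' Ordinary least squares of Cq on log10(input) over a serial dilution
#' (typically six 10-fold points). The per-cycle amplification efficiency is
#' \deqn{E = (10^{-1/slope} - 1) \times 100\%}
#' so a perfectly doubling reaction (slope -1/log10(2) = -3.32 cycles per
#' decade) gives 100%.
#'
#' @param log10_input numeric, log10 of template input per reaction.
#' @param cq numeric, observed quantification cycles.
#' @param assay_id optional label.
#' @param config a [qpcr_config()] supplying validity bounds.
#' @return Tibble with one row: `assay_id`, `slope`, `intercept`,
#'   `efficiency_percent`, `r_squared`, `valid`.
#' @export
amplification_efficiency <- function(log10_input, cq, assay_id = NA_character_,
                                     config = qpcr_config()) {
  keep <- !is.na(log10_input) & !is.na(cq)
  log10_input <- log10_input[keep]
  cq <- cq[keep]
  if (length(unique(log10_input)) < 2) {
    abort("dilution series needs at least two distinct input levels")
  }
  fit <- lm(cq ~ log10_input)
  slope <- unname(coef(fit)[2])
  eff <- (10^(-1 / slope) - 1) * 100
  ss_tot <- sum((cq - mean(cq))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  tibble::tibble(
    assay_id = assay_id,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    efficiency_percent = eff,
    r_squared = r2,
    valid = eff >= config$efficiency_bounds[1] & eff <= config$efficiency_bounds[2]
  )
}

#' Validate all assays of a dilution table
#'
#' @param dilutions tibble with columns `assay_id`,
#'   `input_molecules_per_ul`, `cq`.
#' @param config a [qpcr_config()].
#' @return One validation row per assay, see [amplification_efficiency()].
#' @export
validate_assays <- function(dilutions, config = qpcr_config()) {
  dplyr::bind_rows(lapply(split(dilutions, dilutions$assay_id), function(d) {
    amplification_efficiency(log10(d$input_molecules_per_ul), d$cq,
                             assay_id = d$assay_id[1], config = config)
  }))
}

#' Call amplification of a qPCR well
#'
#' A well amplifies when its Cq is present and at or below `max_cq`, and —
#' when both an expected Tm for the assay and a measured Tm exist — the
#' melt temperature lies within `tm_tolerance` of expectation. A measured
#' Tm with no configured expectation, or a missing Tm measurement, leaves
#' the Cq gate decisive.
#'
#' @param cq numeric vector (NA = no amplification observed).
#' @param tm numeric vector of melt temperatures (NA allowed).
#' @param assay_id character vector (recycled) naming the assay.
#' @param config a [qpcr_config()].
#' @return Logical vector.
#' @export
call_amplification <- function(cq, tm = NA_real_, assay_id = NA_character_,
                               config = qpcr_config()) {
  n <- max(length(cq), length(tm), length(assay_id))
  cq <- rep_len(cq, n)
  tm <- rep_len(tm, n)
  assay_id <- rep_len(assay_id, n)
  expected <- unname(config$expected_tm[assay_id])
  tm_ok <- is.na(expected) | is.na(tm) | abs(tm - expected) <= config$tm_tolerance
  !is.na(cq) & cq <= config$max_cq & tm_ok
}

#' Confirm a fusion by RT-qPCR
#'
#' A fusion assay on a tumor sample is confirmed when at least one tumor
#' replicate amplifies and no control well — matched normal tissue, no
#' template control, carrier-RNA control — amplifies. All three control
#' roles must be present on the plate.
#'
#' @param wells tibble of one assay's wells with columns `role` (`tumor`,
#'   `normal_control`, `ntc`, `carrier_control`), `replicate`, `cq`, `tm`,
#'   and optionally `assay_id`.
#' @param config a [qpcr_config()].
#' @return List with `status` (`"confirmed"`/`"not_confirmed"`) and
#'   `reasons` (character: `NO_TUMOR_AMPLIFICATION` and/or
#'   `CONTROL_AMPLIFIED:<role>`).
#' @export
confirm_fusion <- function(wells, config = qpcr_config()) {
  roles_needed <- c("normal_control", "ntc", "carrier_control")
  missing <- setdiff(roles_needed, unique(wells$role))
  if (length(missing)) {
    abort(sprintf("plate lacks control role(s): %s", paste(missing, collapse = ", ")))
  }
  if (!any(wells$role == "tumor")) {
    abort("plate lacks tumor wells")
  }
  if (!"tm" %in% names(wells)) wells$tm <- NA_real_
  assay <- if ("assay_id" %in% names(wells)) wells$assay_id else NA_character_
  amp <- call_amplification(wells$cq, wells$tm, assay, config)
  tumor_ok <- any(amp[wells$role == "tumor"])
  bad_controls <- sort(unique(wells$role[amp & wells$role != "tumor"]))
  reasons <- c(
    if (!tumor_ok) "NO_TUMOR_AMPLIFICATION",
    if (length(bad_controls)) paste0("CONTROL_AMPLIFIED:", bad_controls)
  )
  list(
    status = if (tumor_ok && !length(bad_controls)) "confirmed" else "not_confirmed",
    reasons = reasons %||% character()
  )
}

#' Confirm every assay of a plate table
#'
#' @param plate tibble with columns `assay_id`, `sample_id`, `role`,
#'   `replicate`, `cq`, `tm`.
#' @param config a [qpcr_config()].
#' @return Tibble: `assay_id`, `status`, `reasons` (collapsed on `;`).
#' @export
confirm_plate <- function(plate, config = qpcr_config()) {
  dplyr::bind_rows(lapply(split(plate, plate$assay_id), function(w) {
    res <- confirm_fusion(w, config)
    tibble::tibble(
      assay_id = w$assay_id[1],
      status = res$status,
      reasons = paste(res$reasons, collapse = ";")
    )
  }))
}

#' Read / write qPCR plate and dilution tables
#'
#' Plate tables are tab-separated with columns `sample_id`, `assay_id`,
#' `role`, `replicate`, `cq`, `tm`; an empty `cq` cell means no
#' amplification. Dilution tables have `assay_id`, `input_molecules_per_ul`,
#' `cq`.
#'
#' @param path file path.
#' @return Tibble.
#' @export
read_plate_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), assay_id = readr::col_character(),
    role = readr::col_character(), replicate = readr::col_integer(),
    cq = readr::col_double(), tm = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_plate_table
#' @param plate plate tibble.
#' @export
write_plate_table <- function(plate, path) {
  readr::write_tsv(plate, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_plate_table
#' @export
read_dilution_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    assay_id = readr::col_character(),
    input_molecules_per_ul = readr::col_double(),
    cq = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_plate_table
#' @param dilutions dilution tibble.
#' @export
write_dilution_table <- function(dilutions, path) {
  readr::write_tsv(dilutions, path, progress = FALSE)
  invisible(path)
}
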