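#' Lesion extent as a percentage
#'
#' Converts a measured volume into a lesion percentage against a reference
#' volume. With `mode = "remaining"` the measurement is the surviving tissue
#' volume and the lesion percent is `100 * (1 - measured / reference)`; with
#' `mode = "lesioned"` the measurement is the damaged volume itself and the
#' percent is `100 * measured / reference`. Values are returned at full
#' precision; round with [round_percent()] (half away from zero, 2 decimals)
#' for table reporting.
#'
#' @param measured Measured volume(s), `>= 0` (units must match `reference`).
#' @param reference Reference volume(s), `> 0` (atlas or whole-structure).
#' @param mode `"remaining"` or `"lesioned"`.
#' @return Numeric percentage(s) in `[0, 100]` for valid input. A remaining
#'   volume exceeding its reference triggers a warning and is clamped to 0%
#'   lesion, with a `"clamped"` attribute marking the affected entries.
#' @examples
#' lesion_percent(330545, 536809, "remaining")   # 38.42... (% lesioned)
#' lesion_percent(244.13, 821.38, "lesioned")    # 29.72...
#' @export
lesion_percent <- function(measured, reference,
                           mode = c("remaining", "lesioned")) {
  mode <- match.arg(mode)
  if (any(reference <= 0)) abort("reference volume must be positive")
  if (any(measured < 0)) abort("measured volume must be non-negative")
  pct <- if (mode == "remaining") {
    100 * (1 - measured / reference)
  } else {
    100 * measured / reference
  }
  clamped <- pct < 0
  if (any(clamped)) {
    warn("remaining volume exceeds reference; lesion percent clamped to 0")
    pct[clamped] <- 0
    attr(pct, "clamped") <- which(clamped)
  }
  pct
}

#' @rdname lesion_percent
#' @param x Numeric percentages.
#' @param digits Decimals (default 2).
#' @export
round_percent <- function(x, digits = 2) round_half_up(x, digits)

#' Per-subject and mean lesion-extent summary
#'
#' Builds a lesion-extent table from per-subject, per-side volume records:
#' per-side percents, a bilateral (summed-volume) percent per subject, and a
#' mean row whose percents derive from the mean measured volumes (matching
#' the printed-table convention). All records must share the same mode and,
#' per side, the same reference volume.
#'
#' @param records Tibble with columns `subject`, `side` (`"left"`/`"right"`),
#'   `mode`, `measured`, `reference`.
#' @return Tibble with one row per subject plus a `"Mean"` row; columns
#'   `subject`, per-side and bilateral measured volumes (rounded to integer)
#'   and percents (rounded to 2 decimals).
#' @examples
#' lesion_table_summary(lesion_volumes_histology())
#' @export
lesion_table_summary <- function(records) {
  stopifnot(all(c("subject", "side", "mode", "measured", "reference") %in%
                  names(records)))
  if (length(unique(records$mode)) != 1) {
    abort("all records must share one mode")
  }
  mode <- records$mode[1]
  if (!all(records$side %in% c("left", "right"))) {
    abort("side must be \"left\" or \"right\"")
  }
  ref_by_side <- records |>
    group_by(.data$side) |>
    summarise(n_ref = length(unique(.data$reference)),
              reference = .data$reference[1], .groups = "drop")
  if (any(ref_by_side$n_ref != 1)) {
    abort("inconsistent reference volumes within a side")
  }
  wide <- records |>
    select("subject", "side", "measured") |>
    tidyr::pivot_wider(names_from = "side", values_from = "measured")
  ref_l <- ref_by_side$reference[ref_by_side$side == "left"]
  ref_r <- ref_by_side$reference[ref_by_side$side == "right"]
  per_subject <- wide |>
    mutate(bilateral = .data$left + .data$right,
           left_pct = lesion_percent(.data$left, ref_l, mode),
           right_pct = lesion_percent(.data$right, ref_r, mode),
           total_pct = lesion_percent(.data$bilateral, ref_l + ref_r, mode))
  # mean percents average the (2-dp rounded) per-subject percents, the
  # printed-table convention; with a shared reference this differs from the
  # percent of the mean volume only in the third decimal
  mean_row <- tibble(
    subject = "Mean",
    left = mean(per_subject$left),
    right = mean(per_subject$right),
    bilateral = mean(per_subject$bilateral),
    left_pct = mean(round_percent(per_subject$left_pct)),
    right_pct = mean(round_percent(per_subject$right_pct)),
    total_pct = mean(round_percent(per_subject$total_pct))
  )
  bind_rows(mean_row, per_subject) |>
    mutate(left = round_half_up(.data$left, 0),
           right = round_half_up(.data$right, 0),
           bilateral = round_half_up(.data$bilateral, 0),
           left_pct = round_percent(.data$left_pct),
           right_pct = round_percent(.data$right_pct),
           total_pct = round_percent(.data$total_pct))
}

#' Bundled lesion-volume records
#'
#' Volumetry records for the five hippocampal-lesion macaques of the study
#' this package's defaults emulate. `lesion_volumes_histology()` holds the
#' remaining hippocampal tissue volumes measured from Nissl-stained sections
#' registered to atlas sections, against the atlas hemisphere volumes
#' (`mode = "remaining"`, arbitrary consistent units).
#' `lesion_volumes_t2()` holds the lesioned volumes measured from
#' T2-weighted hypersignal against each animal's whole hippocampal volume
#' (`mode = "lesioned"`, mm^3-scale units; references differ per subject, so
#' these records are summarised with [lesion_percent()] directly rather than
#' [lesion_table_summary()]).
#'
#' @return A tibble of per-subject, per-side records.
#' @export
lesion_volumes_histology <- function() {
  atlas_left <- 268144
  atlas_right <- 268665
  remaining <- tibble::tribble(
    ~subject, ~left,  ~right,
    "E",      184498, 146047,
    "M",      129741, 84877,
    "N",      159535, 158787,
    "S",      94769,  89512,
    "T",      178354, 130254
  )
  remaining |>
    tidyr::pivot_longer(c("left", "right"), names_to = "side",
                        values_to = "measured") |>
    mutate(mode = "remaining",
           reference = ifelse(.data$side == "left", atlas_left, atlas_right)) |>
    select("subject", "side", "mode", "measured", "reference")
}

#' @rdname lesion_volumes_histology
#' @export
lesion_volumes_t2 <- function() {
  tibble::tribble(
    ~subject, ~side,       ~measured, ~reference,
    "E",      "total",     244.13,    821.38,
    "E",      "left",      94.88,     429.25,
    "E",      "right",     149.25,    392.13,
    "M",      "total",     563.38,    1019.75,
    "M",      "left",      190.50,    516.63,
    "M",      "right",     372.88,    503.13,
    "N",      "total",     179.50,    1161.38,
    "N",      "left",      109.38,    607.63,
    "N",      "right",     70.13,     553.75,
    "S",      "total",     706.49,    979.24,
    "S",      "left",      398.37,    484.12,
    "S",      "right",     308.12,    495.12,
    "T",      "total",     690.63,    937.38,
    "T",      "left",      364.00,    442.88,
    "T",      "right",     326.63,    494.50
  ) |>
    mutate(mode = "lesioned") |>
    select("subject", "side", "mode", "measured", "reference")
}
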