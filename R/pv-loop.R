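#' Pressure-volume-loop quantities
#'
#' Forward model of the idealised pressure-volume loop with a linear
#' end-systolic pressure-volume relation through (V0, 0) and the
#' potential-energy triangle approximated as 0.5 * Pes * (ESV - V0):
#'
#' * end-systolic elastance  `ees = pes / (esv - v0)`  (mmHg/mL)
#' * effective arterial elastance  `ea = pes / sv`  (mmHg/mL)
#' * external work  `ew = pes * sv`  (mmHg*mL)
#' * pressure-volume area  `pva = ew + 0.5 * pes * (esv - v0)`
#' * efficiency  `eff = ew / pva`
#' * ejection fraction  `ef = sv / edv`
#'
#' with `sv = edv - esv`. This is the independent oracle for the
#' coupling-based ejection-fraction shortcut: at `v0 = 0` the shortcut is
#' algebraically exact, and [ef_shortcut_gap()] quantifies its error when
#' `v0 > 0`.
#'
#' @param loops A data frame with columns `edv`, `esv`, `pes` and optionally
#'   `v0` (mL and mmHg; `v0` defaults to 0). Must satisfy
#'   `edv > esv > v0 >= 0` and `pes > 0` in every row. Extra columns are
#'   preserved.
#' @return The input as a tibble with columns `sv`, `ees`, `ea`, `ew`,
#'   `pva`, `eff`, `ef` appended.
#' @examples
#' pv_quantities(tibble::tibble(edv = 120, esv = 60, v0 = 0, pes = 90))
#' @export
pv_quantities <- function(loops) {
  loops <- as_tibble(loops)
  required <- c("edv", "esv", "pes")
  missing <- setdiff(required, names(loops))
  if (length(missing)) {
    abort(paste0("`loops` is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "efcoupling_schema_error")
  }
  if (!"v0" %in% names(loops)) loops$v0 <- 0

  with(loops, {
    if (any(v0 < 0)) {
      abort("`v0` must be non-negative.", class = "efcoupling_invalid_input")
    }
    if (any(esv < v0)) {
      abort("`esv` must be at least `v0` (loop cannot cross the ESPVR intercept).",
            class = "efcoupling_invalid_input")
    }
    if (any(esv == v0)) {
      abort("Degenerate loop: `esv` equals `v0` (infinite end-systolic elastance).",
            class = "efcoupling_degenerate_loop")
    }
    if (any(edv <= esv)) {
      abort("`edv` must exceed `esv` (stroke volume must be positive).",
            class = "efcoupling_invalid_input")
    }
    if (any(pes <= 0)) {
      abort("`pes` must be positive.", class = "efcoupling_invalid_input")
    }
  })

  dplyr::mutate(
    loops,
    sv  = .data$edv - .data$esv,
    ees = .data$pes / (.data$esv - .data$v0),
    ea  = .data$pes / .data$sv,
    ew  = .data$pes * .data$sv,
    pva = .data$ew + 0.5 * .data$pes * (.data$esv - .data$v0),
    eff = .data$ew / .data$pva,
    ef  = .data$sv / .data$edv
  )
}

#' Error of the efficiency-based ejection-fraction shortcut
#'
#' The shortcut `ef_from_efficiency(eff)` equals the true loop ejection
#' fraction SV/EDV exactly when the unstressed volume V0 is zero; for
#' V0 > 0 it overestimates it. This returns the signed gap
#' `ef_from_efficiency(eff) - ef`, both computed from [pv_quantities()]:
#' exactly 0 at `v0 = 0`, strictly positive for `v0 > 0`, and increasing
#' in `v0` at fixed volumes and pressure.
#'
#' @inheritParams pv_quantities
#' @return The input as a tibble with `eff`, `ef` and the signed
#'   `ef_shortcut_gap` column appended.
#' @examples
#' ef_shortcut_gap(tibble::tibble(edv = 150, esv = 75, v0 = 15, pes = 100))
#' # gap = 5/9 - 1/2 = 1/18
#' @export
ef_shortcut_gap <- function(loops) {
  q <- pv_quantities(loops)
  dplyr::mutate(q, ef_shortcut_gap = ef_from_efficiency(.data$eff) - .data$ef)
}

#' Plot a set of idealised pressure-volume loops
#'
#' Draws each loop as a rectangle (the external-work area) together with the
#' end-systolic pressure-volume relation through (V0, 0), whose triangle
#' with the loop's left border is the potential-energy term of the
#' pressure-volume area.
#'
#' @inheritParams pv_quantities
#' @param max_loops Cap on the number of loops drawn (default 12).
#' @return A ggplot object.
#' @export
plot_pv_loops <- function(loops, max_loops = 12) {
  q <- pv_quantities(loops)
  q$loop_id <- factor(seq_len(nrow(q)))
  q <- q[seq_len(min(nrow(q), max_loops)), ]
  rects <- q
  espvr <- tidyr::pivot_longer(
    dplyr::transmute(q, .data$loop_id, x0 = .data$v0, y0 = 0,
                     x1 = .data$esv, y1 = .data$pes),
    cols = -"loop_id", names_to = c(".value", "pt"),
    names_pattern = "(.)(.)"
  )
  ggplot2::ggplot(rects) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$esv, xmax = .data$edv, ymin = 0,
                   ymax = .data$pes, fill = .data$loop_id),
      alpha = 0.25, colour = "grey30"
    ) +
    ggplot2::geom_line(
      data = espvr,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$loop_id,
                   colour = .data$loop_id),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "Volume (mL)", y = "Pressure (mmHg)",
                  fill = "loop", colour = "loop") +
    ggplot2::theme_minimal()
}
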