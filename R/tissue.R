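#' Tissue relaxation, flow and diffusion parameters
#'
#' Container for the per-tissue constants driving the sequence simulation:
#' longitudinal and transverse relaxation times, mean absolute flow speed and
#' apparent diffusion coefficient, at a given field strength.
#'
#' @param name tissue label, one of `"vw"` (vessel wall), `"csf"`, `"blood"`,
#'   or any custom label.
#' @param t1_ms longitudinal relaxation time (ms); must exceed `t2_ms`.
#' @param t2_ms transverse relaxation time (ms); must be positive.
#' @param mean_speed_cm_s mean absolute velocity (cm/s), >= 0.
#' @param diffusion_mm2_s apparent diffusion coefficient (mm^2/s), >= 0.
#' @param field_t field strength label (`"3T"` or `"7T"`), informational.
#' @return An object of class `tissue_params`.
#' @examples
#' csf7 <- tissue_preset("csf", "7T")
#' csf7$t2_ms   # 311
#' @export
tissue_params <- function(name, t1_ms, t2_ms, mean_speed_cm_s = 0,
                          diffusion_mm2_s = 0, field_t = "custom") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(t1_ms) || !is.finite(t2_ms) || t2_ms <= 0 || t1_ms <= t2_ms)
    stop("require t1_ms > t2_ms > 0")
  if (mean_speed_cm_s < 0 || diffusion_mm2_s < 0)
    stop("mean_speed_cm_s and diffusion_mm2_s must be >= 0")
  structure(list(name = name, t1_ms = t1_ms, t2_ms = t2_ms,
                 mean_speed_cm_s = mean_speed_cm_s,
                 diffusion_mm2_s = diffusion_mm2_s, field_t = field_t),
            class = "tissue_params")
}

#' Packaged tissue presets
#'
#' Returns the vessel wall, CSF or blood constants used throughout the
#' simulations, read from the packaged preset table. Values are literature
#' constants for the two field strengths (e.g. CSF at 7T: T1 4019 ms,
#' T2 311 ms, D 3e-3 mm^2/s, mean speed 0.367 cm/s).
#'
#' @param name `"vw"`, `"csf"` or `"blood"`.
#' @param field_t `"3T"` or `"7T"`.
#' @return A `tissue_params` object.
#' @export
tissue_preset <- function(name = c("vw", "csf", "blood"),
                          field_t = c("7T", "3T")) {
  name <- match.arg(name)
  field_t <- match.arg(field_t)
  tab <- tissue_preset_table()
  row <- tab[tab$name == name & tab$field_t == field_t, ]
  tissue_params(row$name, row$t1_ms, row$t2_ms, row$mean_speed_cm_s,
                row$diffusion_mm2_s, row$field_t)
}

#' @rdname tissue_preset
#' @export
tissue_preset_table <- function() {
  f <- system.file("extdata", "tissue_presets.csv", package = "vwisim",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("Tissue '%s' (%s): T1 %.0f ms, T2 %.0f ms, <|v|> %.3g cm/s, D %.3g mm^2/s\n",
              x$name, x$field_t, x$t1_ms, x$t2_ms, x$mean_speed_cm_s,
              x$diffusion_mm2_s))
  invisible(x)
}
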