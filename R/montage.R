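#' Standard 10--20 electrode montage on the unit sphere
#'
#' Builds unit-sphere positions for the 21-channel neonatal 10--20 montage
#' (Fp1, Fp2, F7, F3, Fz, F4, F8, M1, T3, C3, Cz, C4, T4, M2, T5, P3, Pz,
#' P4, T6, O1, O2) from the geometric 10--20 construction: midline electrodes
#' at 10/30/50/70/90 % of the nasion--inion arc, the outer ring at 72 degrees
#' inclination from the vertex spaced every 36 degrees, and the intermediate
#' electrodes (F3/F4, C3/C4, P3/P4) as great-circle midpoints between the
#' midline and the ring. Mastoids (M1/M2) sit slightly below the equator.
#'
#' Coordinates: `x` right, `y` anterior, `z` up, unit radius.
#'
#' @param labels Optional character vector to subset/reorder the montage.
#' @return A tibble with columns `label`, `x`, `y`, `z`, `hemisphere`
#'   (`"left"`, `"right"`, `"midline"`).
#' @export
montage_1020 <- function(labels = NULL) {
  # direction from inclination (from +z) and azimuth (from +y, towards +x)
  dir <- function(incl, az) {
    i <- incl * pi / 180; a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  mid <- function(u, v) { w <- u + v; w / sqrt(sum(w^2)) }

  p <- list(
    Fpz = dir(72, 0), Fz = dir(36, 0), Cz = dir(0, 0),
    Pz = dir(36, 180), Oz = dir(72, 180),
    Fp1 = dir(72, -18), Fp2 = dir(72, 18),
    F7 = dir(72, -54), F8 = dir(72, 54),
    T3 = dir(72, -90), T4 = dir(72, 90),
    T5 = dir(72, -126), T6 = dir(72, 126),
    O1 = dir(72, -162), O2 = dir(72, 162),
    M1 = dir(100, -100), M2 = dir(100, 100)
  )
  p$F3 <- mid(p$Fz, p$F7); p$F4 <- mid(p$Fz, p$F8)
  p$C3 <- mid(p$Cz, p$T3); p$C4 <- mid(p$Cz, p$T4)
  p$P3 <- mid(p$Pz, p$T5); p$P4 <- mid(p$Pz, p$T6)

  order21 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "M1", "T3", "C3",
               "Cz", "C4", "T4", "M2", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  xyz <- do.call(rbind, p[order21])
  out <- tibble::tibble(
    label = order21,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hemisphere = channel_hemisphere(order21)
  )
  if (!is.null(labels)) {
    missing <- setdiff(labels, out$label)
    if (length(missing) > 0) {
      ckc_stop(paste0("channels not in montage: ", paste(missing, collapse = ", ")),
               "montage_error")
    }
    out <- out[match(labels, out$label), ]
  }
  out
}

#' Hemisphere of a 10--20 channel label
#'
#' Odd final digits are left-hemisphere, even are right, `z`-suffixed labels
#' are midline; M1/M2 follow the same digit rule.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector, `"left"`, `"right"` or `"midline"`.
#' @export
channel_hemisphere <- function(labels) {
  last <- substr(labels, nchar(labels), nchar(labels))
  digit <- suppressWarnings(as.integer(last))
  ifelse(is.na(digit), "midline", ifelse(digit %% 2 == 1, "left", "right"))
}

#' Cortical parcel metadata table
#'
#' The 58-parcel scheme used for source-space network analysis: 29 parcels per
#' hemisphere, each labelled by lobe (F frontal, C central, T temporal,
#' O occipital) and an index, e.g. `L_C3`. Lobe counts per hemisphere are
#' F 8, C 8, T 7, O 6.
#'
#' @return A tibble with columns `label`, `hemisphere`, `lobe`.
#' @export
parcel_table <- function() {
  lobes <- c(rep("F", 8), rep("C", 8), rep("T", 7), rep("O", 6))
  idx <- unlist(lapply(rle(lobes)$lengths, seq_len))
  one <- function(h) tibble::tibble(
    label = paste0(h, "_", lobes, idx),
    hemisphere = ifelse(h == "L", "left", "right"),
    lobe = lobes
  )
  dplyr::bind_rows(one("L"), one("R"))
}
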