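#' Electrode layout of a planar 8 x 8 MEA
#'
#' Builds the standard 60-slot layout of a planar micro-electrode array: an
#' 8 x 8 grid with the four corner positions excluded. Electrode ids are
#' 0-based and contiguous; one slot (typically the reference electrode) may be
#' left without spikes in a recording, so analyses are written against the
#' number of analysis slots (60), not the number of physically active
#' electrodes.
#'
#' @param n_electrodes number of analysis slots; must equal the number of
#'   non-corner grid positions (60 for the 8 x 8 grid).
#' @param inter_electrode_distance center-to-center electrode pitch in
#'   micrometers.
#' @return an object of class `mea_layout`: a list with `n_electrodes`,
#'   `positions` (data.frame `id`, `row`, `col`) and
#'   `inter_electrode_distance`.
#' @export
electrode_layout <- function(n_electrodes = 60L, inter_electrode_distance = 200) {
  grid <- expand.grid(row = 1:8, col = 1:8)
  corner <- (grid$row %in% c(1, 8)) & (grid$col %in% c(1, 8))
  grid <- grid[!corner, , drop = FALSE]
  grid <- grid[order(grid$col, grid$row), ]
  if (n_electrodes != nrow(grid)) {
    stop("n_electrodes must be ", nrow(grid), " for the 8 x 8 corner-less grid")
  }
  positions <- data.frame(id = seq_len(nrow(grid)) - 1L,
                          row = grid$row, col = grid$col)
  structure(list(n_electrodes = as.integer(n_electrodes),
                 positions = positions,
                 inter_electrode_distance = inter_electrode_distance),
            class = "mea_layout")
}

#' @export
print.mea_layout <- function(x, ...) {
  cat("MEA layout:", x$n_electrodes, "electrodes, 8 x 8 grid (corners excluded),",
      x$inter_electrode_distance, "um pitch\n")
  invisible(x)
}
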