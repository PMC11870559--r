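# Spatial substrate: 2D Moore lattice, tumor occupancy counts, and one
# scalar cytokine field per species. Matrices are indexed [row, col].

#' Create an empty lattice tumor microenvironment
#'
#' @param cfg A [grid_config()].
#' @param cytokines Named list of [cytokine_params()]; one scalar field
#'   is allocated per species at its `initial_level`.
#' @return A `tme_grid`: the config plus a `tumor_count` integer matrix
#'   and a named list `cytokine` of numeric matrices.
#' @export
tme_grid <- function(cfg = grid_config(), cytokines = list()) {
  fields <- lapply(cytokines, function(p)
    matrix(p$initial_level, nrow = cfg$height, ncol = cfg$width))
  structure(list(cfg = cfg,
                 tumor_count = matrix(0L, cfg$height, cfg$width),
                 cytokine = fields,
                 cyt_params = cytokines),
            class = "tme_grid")
}

in_grid <- function(cfg, row, col) {
  row >= 1L & row <= cfg$height & col >= 1L & col <= cfg$width
}

#' Moore neighborhood of a lattice position
#'
#' All positions within Chebyshev distance `radius` of `pos`, clipped at
#' the grid borders. The center is excluded unless `include_self = TRUE`.
#'
#' @param cfg A [grid_config()].
#' @param pos Integer `c(row, col)`, 1-based.
#' @param radius Non-negative integer Chebyshev radius.
#' @param include_self Keep `pos` itself in the result?
#' @return A two-column integer matrix of `(row, col)` positions.
#' @export
moore_neighborhood <- function(cfg, pos, radius = 1L, include_self = FALSE) {
  pos <- as.integer(pos)
  if (!in_grid(cfg, pos[1], pos[2]))
    stop("position (", pos[1], ",", pos[2], ") outside grid")
  stopifnot(radius >= 0L)
  rows <- max(1L, pos[1] - radius):min(cfg$height, pos[1] + radius)
  cols <- max(1L, pos[2] - radius):min(cfg$width, pos[2] + radius)
  out <- as.matrix(expand.grid(row = rows, col = cols))
  if (!include_self && radius >= 1L)
    out <- out[!(out[, 1] == pos[1] & out[, 2] == pos[2]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# Border-clipped neighborhood sum of a matrix: for every position, the
# sum of entries within Chebyshev radius r (including self). Used to
# compute local tumor load for all agents at once.
nbhd_sum <- function(mat, radius = 1L) {
  if (radius == 0L) return(mat)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (dr in -radius:radius) {
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    rd <- max(1L, 1L - dr):min(nr, nr - dr)
    for (dc in -radius:radius) {
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      cd <- max(1L, 1L - dc):min(nc, nc - dc)
      out[rd, cd] <- out[rd, cd] + mat[rs, cs]
    }
  }
  out
}

#' Local tumor load and cytokine level at a position
#'
#' `b_local` sums tumor occupancy over the Moore neighborhood of
#' `radius` including the center. `c_local` is the total cytokine level
#' (summed over species) at the position itself (`c_radius = 0`, the
#' default) or averaged over the neighborhood.
#'
#' @param grid A `tme_grid`.
#' @param pos Integer `c(row, col)`.
#' @param radius Neighborhood radius for the tumor count.
#' @param c_radius Neighborhood radius for the cytokine readout.
#' @return `list(b_local =, c_local =)`.
#' @export
local_state <- function(grid, pos, radius = 1L, c_radius = 0L) {
  cfg <- grid$cfg
  nb <- moore_neighborhood(cfg, pos, radius, include_self = TRUE)
  b_local <- sum(grid$tumor_count[nb])
  ctot <- total_cytokine(grid)
  if (c_radius == 0L) {
    c_local <- ctot[pos[1], pos[2]]
  } else {
    nbc <- moore_neighborhood(cfg, pos, c_radius, include_self = TRUE)
    c_local <- mean(ctot[nbc])
  }
  list(b_local = b_local, c_local = c_local)
}

total_cytokine <- function(grid) {
  if (!length(grid$cytokine))
    return(matrix(0, grid$cfg$height, grid$cfg$width))
  Reduce(`+`, grid$cytokine)
}

#' One decay-and-deposit update of a cytokine field
#'
#' Every lattice cell decays by the factor `2^(-dt / half_life)`; then
#' `deposit_per_step` is added at each armored-NK position (a position
#' occupied by k armored agents receives k deposits).
#'
#' @param field Numeric matrix, the current field.
#' @param params A [cytokine_params()].
#' @param dt Step length in hours.
#' @param deposit_rows,deposit_cols Integer vectors of armored NK
#'   positions (parallel; may repeat).
#' @return The updated field matrix.
#' @export
cytokine_step <- function(field, params, dt, deposit_rows = integer(),
                          deposit_cols = integer()) {
  stopifnot(params$half_life > 0)
  if (params$deposit_per_step < 0) stop("negative cytokine deposit")
  field <- field * 2^(-dt / params$half_life)
  if (length(deposit_rows)) {
    lin <- (deposit_cols - 1L) * nrow(field) + deposit_rows
    acc <- tabulate(lin, nbins = length(field)) * params$deposit_per_step
    field <- field + matrix(acc, nrow(field), ncol(field))
  }
  field
}

#' Update all cytokine fields of a lattice
#'
#' @param grid A `tme_grid`.
#' @param armored Named list mapping species name to a two-column matrix
#'   of armored-NK positions depositing that species this step.
#' @return The grid with all fields decayed and deposits applied.
#' @export
update_cytokine_field <- function(grid, armored = list()) {
  dt <- grid$cfg$dt
  for (sp in names(grid$cytokine)) {
    pos <- armored[[sp]]
    if (is.null(pos)) pos <- matrix(integer(), 0, 2)
    grid$cytokine[[sp]] <- cytokine_step(grid$cytokine[[sp]],
                                         grid$cyt_params[[sp]], dt,
                                         pos[, 1], pos[, 2])
  }
  grid
}

#' Does a grid cell have spare tumor capacity?
#'
#' @param grid A `tme_grid`.
#' @param pos Integer `c(row, col)`.
#' @return `TRUE` iff the tumor count at `pos` is below `b_max`.
#' @export
check_capacity <- function(grid, pos) {
  if (!in_grid(grid$cfg, pos[1], pos[2]))
    stop("position (", pos[1], ",", pos[2], ") outside grid")
  grid$tumor_count[pos[1], pos[2]] < grid$cfg$b_max
}

#' Write a lattice field snapshot to CSV
#'
#' Dense row-major matrix dump of the tumor-occupancy or a cytokine
#' field, one file per recorded step.
#'
#' @param mat Matrix to write.
#' @param path Output file path.
#' @export
write_field_csv <- function(mat, path) {
  utils::write.table(mat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}
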