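#' Local 3x3 pattern bases
#'
#' Spatial basis patterns used to synthesize local parameter variation
#' around a center voxel. Each basis is a 9-element vector over the 3x3
#' neighbourhood in row-major order (rows concatenated; the center voxel
#' is element 5) and has a zero center, so linear combinations never move
#' the center value:
#'
#' * `u1` — flat (all zeros): uniform neighbourhood;
#' * `u2`, `u3` — horizontal / vertical linear ramps;
#' * `u4`, `u5`, `u6` — quadratic terms (column, row, cross curvature).
#'
#' The three supported modes select nested subsets: `M = 1` (flat,
#' `u1`), `M = 3` (linear, `u1..u3`), `M = 6` (quadratic, `u1..u6`).
#'
#' @param mode Number of bases: 1, 3 or 6, or one of `"flat"`,
#'   `"linear"`, `"quadratic"`.
#' @return An `M x 9` numeric matrix, rows named `u1..uM`.
#' @examples
#' xq_bases(3)
#' @export
xq_bases <- function(mode = 6) {
  m <- basis_mode(mode)
  U <- rbind(
    u1 = c( 0,  0,  0,   0, 0,  0,   0,  0,  0),
    u2 = c(-1,  0,  1,  -1, 0,  1,  -1,  0,  1),
    u3 = c(-1, -1, -1,   0, 0,  0,   1,  1,  1),
    u4 = c( 1,  0,  1,   1, 0,  1,   1,  0,  1),
    u5 = c( 1,  1,  1,   0, 0,  0,   1,  1,  1),
    u6 = c( 1,  0, -1,   0, 0,  0,  -1,  0,  1)
  )
  U[seq_len(m), , drop = FALSE]
}

#' @rdname xq_bases
#' @return `basis_mode()`: the validated integer M.
#' @export
basis_mode <- function(mode) {
  if (is.character(mode))
    mode <- c(flat = 1, linear = 3, quadratic = 6)[[match.arg(mode, c("flat", "linear", "quadratic"))]]
  mode <- as.integer(mode)
  if (!mode %in% c(1L, 3L, 6L))
    stop("basis mode must be 1 (flat), 3 (linear) or 6 (quadratic)", call. = FALSE)
  mode
}

## row-major index of the center voxel of the 3x3 neighbourhood
.CENTER_IDX <- 5L
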