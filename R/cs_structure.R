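#' Structured measurement-matrix family for a switched sensor array
#'
#' Describes the feasible class of binary compressed-sensing matrices for a
#' circular sensor array whose sensors are wired in blocks sharing one
#' multiplexing switch: each measurement row may activate at most one sensor
#' per block, and measurements act independently on consecutive groups of
#' `block_size * blocks_per_group` sensors.
#'
#' @param block_size Sensors sharing one switch (default 4).
#' @param blocks_per_group Blocks summed into one measurement channel
#'   (default 4), so the group size is `block_size * blocks_per_group`.
#' @param num_groups Independent sensor groups on the ring (default 4).
#' @param m0 Measurements taken per group.
#'
#' @return An object of class `cs_structure` with fields `block_size`,
#'   `blocks_per_group`, `num_groups`, `m0` and the derived sizes `n0`
#'   (sensors per group), `n` (total sensors) and `m` (total measurements).
#' @examples
#' cs_structure(m0 = 12)  # the 64-sensor instrument layout, 12 of 16 rows
#' @export
cs_structure <- function(block_size = 4, blocks_per_group = 4,
                         num_groups = 4, m0) {
  for (v in list(block_size, blocks_per_group, num_groups, m0)) {
    if (length(v) != 1 || !is.numeric(v) || v < 1 || v != round(v)) {
      stop("all cs_structure counts must be positive integers", call. = FALSE)
    }
  }
  n0 <- block_size * blocks_per_group
  if (m0 > n0) {
    stop("m0 cannot exceed the group size n0 = ", n0, call. = FALSE)
  }
  structure(
    list(
      block_size = as.integer(block_size),
      blocks_per_group = as.integer(blocks_per_group),
      num_groups = as.integer(num_groups),
      m0 = as.integer(m0),
      n0 = as.integer(n0),
      n = as.integer(n0 * num_groups),
      m = as.integer(m0 * num_groups)
    ),
    class = "cs_structure"
  )
}

#' @export
print.cs_structure <- function(x, ...) {
  cat(sprintf(
    "<cs_structure> block_size=%d, blocks_per_group=%d (n0=%d), num_groups=%d, m0=%d (m=%d, n=%d)\n",
    x$block_size, x$blocks_per_group, x$n0, x$num_groups, x$m0, x$m, x$n
  ))
  invisible(x)
}

#' Validate a selection list
#'
#' A selection list names, for every measurement row and every block, the
#' active sensor within the block; `0` means the block is switched off for
#' that row.
#'
#' @param selection Integer matrix, `m0` rows by `blocks_per_group` columns,
#'   entries in `0:block_size`.
#' @param structure A [cs_structure()].
#' @return The selection, invisibly, after validation.
#' @export
validate_selection <- function(selection, structure) {
  stopifnot(inherits(structure, "cs_structure"))
  selection <- as.matrix(selection)
  if (nrow(selection) != structure$m0 ||
      ncol(selection) != structure$blocks_per_group) {
    stop(sprintf(
      "selection must be %d x %d (rows x blocks), got %d x %d",
      structure$m0, structure$blocks_per_group,
      nrow(selection), ncol(selection)
    ), call. = FALSE)
  }
  bad <- which(!(selection %in% 0:structure$block_size) |
                 selection != round(selection))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(selection)) + 1
    b <- ((bad[1] - 1) %/% nrow(selection)) + 1
    stop(sprintf(
      "invalid selection entry %s at row %d, block %d (allowed: 0..%d)",
      format(selection[bad[1]]), i, b, structure$block_size
    ), call. = FALSE)
  }
  invisible(selection)
}

#' Build a group measurement matrix from a selection list
#'
#' Produces the binary `m0 x n0` matrix in which row `i` has a 1 in column
#' `(b - 1) * block_size + c` exactly when block `b` of row `i` selects
#' sensor `c`; switched-off blocks contribute zeros.
#'
#' @inheritParams validate_selection
#' @return A binary matrix of class `group_matrix` with attributes
#'   `structure` and `selection`.
#' @examples
#' st <- cs_structure(m0 = 2)
#' sel <- rbind(c(1, 0, 1, 2), c(4, 1, 4, 0))
#' make_cs_matrix(sel, st)
#' @export
make_cs_matrix <- function(selection, structure) {
  selection <- validate_selection(selection, structure)
  M <- matrix(0, structure$m0, structure$n0)
  act <- which(selection > 0, arr.ind = TRUE)
  if (nrow(act)) {
    cols <- (act[, 2] - 1L) * structure$block_size + selection[act]
    M[cbind(act[, 1], cols)] <- 1
  }
  structure(M, class = c("group_matrix", "matrix", "array"),
            structure = structure, selection = selection)
}

#' Check the block feasibility constraint
#'
#' A matrix is feasible for a structure when it is binary, has shape
#' `m0 x n0`, and every row has at most one nonzero entry inside each
#' contiguous block of `block_size` columns (one switch can route at most
#' one sensor).
#'
#' @param M Numeric matrix, `m0 x n0`.
#' @param structure A [cs_structure()].
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(M, structure) {
  stopifnot(inherits(structure, "cs_structure"))
  M <- unclass(as.matrix(M))
  if (nrow(M) != structure$m0 || ncol(M) != structure$n0) {
    stop(sprintf("matrix must be %d x %d, got %d x %d",
                 structure$m0, structure$n0, nrow(M), ncol(M)),
         call. = FALSE)
  }
  if (!all(M %in% c(0, 1))) return(FALSE)
  blk <- rep(seq_len(structure$blocks_per_group),
             each = structure$block_size)
  for (b in seq_len(structure$blocks_per_group)) {
    if (any(rowSums(M[, blk == b, drop = FALSE]) > 1)) return(FALSE)
  }
  TRUE
}

#' Draw a uniformly random feasible matrix
#'
#' Each (row, block) cell independently selects one of the `block_size + 1`
#' possibilities off, sensor 1, ..., sensor `block_size`, each with equal
#' probability, so every feasible matrix (including matrices with inactive
#' blocks or all-zero rows) has positive probability.
#'
#' Uses R's global RNG stream; call [set.seed()] for reproducibility.
#'
#' @param structure A [cs_structure()].
#' @return A list with elements `selection` and `matrix` (a `group_matrix`).
#' @export
sample_feasible_matrix <- function(structure) {
  stopifnot(inherits(structure, "cs_structure"))
  sel <- matrix(
    sample.int(structure$block_size + 1L,
               structure$m0 * structure$blocks_per_group,
               replace = TRUE) - 1L,
    nrow = structure$m0
  )
  list(selection = sel, matrix = make_cs_matrix(sel, structure))
}

#' Assemble the block-diagonal matrix acting on the full ring
#'
#' The measurement channels of different groups are electrically independent,
#' so the matrix acting on all `n = n0 * num_groups` sensors is block
#' diagonal with the group matrices on the diagonal.
#'
#' @param groups A single `group_matrix` (replicated across groups) or a list
#'   of `num_groups` matrices sharing one structure.
#' @return A binary `(num_groups * m0) x (num_groups * n0)` matrix of class
#'   `block_diagonal_matrix`, with attributes `structure` and `groups`.
#' @export
assemble_block_diagonal <- function(groups) {
  if (inherits(groups, "group_matrix")) {
    st <- attr(groups, "structure")
    groups <- rep(list(groups), st$num_groups)
  }
  stopifnot(is.list(groups), length(groups) >= 1)
  st <- attr(groups[[1]], "structure")
  if (is.null(st)) stop("group matrices must carry a cs_structure", call. = FALSE)
  dims <- vapply(groups, dim, integer(2))
  if (any(dims[1, ] != st$m0) || any(dims[2, ] != st$n0)) {
    stop("group matrices have inconsistent shapes", call. = FALSE)
  }
  k <- length(groups)
  A <- matrix(0, k * st$m0, k * st$n0)
  for (g in seq_len(k)) {
    A[(g - 1) * st$m0 + seq_len(st$m0),
      (g - 1) * st$n0 + seq_len(st$n0)] <- unclass(groups[[g]])
  }
  structure(A, class = c("block_diagonal_matrix", "matrix", "array"),
            structure = st, groups = groups)
}
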