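#' Construct a landscape object
#'
#' A landscape couples a land-use raster (integer codes, see
#' [land_use_classes()]), a patch-id raster of the same shape, a logical
#' agricultural-buffer-zone (ABZ) layer and the patch table. Patches are
#' maximal 4-connected sets of cells sharing one land-use class. Coordinates
#' are (row, col) with row 1 the top raster row.
#'
#' @param land_use Integer matrix of land-use codes (0-5).
#' @param patch_id Integer matrix of positive patch ids, same shape.
#' @param patch_table Data frame with columns `patch_id`, `land_use`
#'   (class name) and `area_cells`. Derived from the rasters when `NULL`.
#' @param cell_size_m Cell edge length in meters (default 20).
#' @param abz Logical matrix of ABZ flags; all `FALSE` when `NULL`.
#' @param validate Check all landscape invariants (default `TRUE`).
#' @return An object of class `bee_landscape`.
#' @export
landscape <- function(land_use, patch_id = NULL, patch_table = NULL,
                      cell_size_m = 20, abz = NULL, validate = TRUE) {
  land_use <- as.matrix(land_use)
  attr(land_use, "header") <- NULL
  storage.mode(land_use) <- "integer"
  if (is.null(patch_id)) {
    patch_id <- matrix(cpp_label4(as.integer(land_use), nrow(land_use),
                                  ncol(land_use)),
                       nrow(land_use), ncol(land_use))
  }
  patch_id <- as.matrix(patch_id)
  attr(patch_id, "header") <- NULL
  storage.mode(patch_id) <- "integer"
  if (is.null(abz)) abz <- matrix(FALSE, nrow(land_use), ncol(land_use))
  if (is.null(patch_table)) patch_table <- derive_patch_table(land_use, patch_id)
  ls <- structure(
    list(n_rows = nrow(land_use), n_cols = ncol(land_use),
         cell_size_m = cell_size_m, land_use = land_use,
         patch_id = patch_id, abz = abz, patch_table = patch_table),
    class = "bee_landscape")
  if (validate) validate_landscape(ls)
  ls
}

derive_patch_table <- function(land_use, patch_id) {
  ids <- sort(unique(as.integer(patch_id)))
  area <- tabulate(match(as.integer(patch_id), ids))
  lu <- as.integer(land_use)[match(ids, as.integer(patch_id))]
  data.frame(patch_id = ids, land_use = lu_name_of(lu), area_cells = area,
             stringsAsFactors = FALSE)
}

#' Validate landscape invariants
#'
#' Checks that the rasters share one shape, land-use codes are known, every
#' patch id in the raster appears in the patch table with the correct area
#' and a single land-use class, and ABZ flags sit on arable cells only.
#' Each violation raises a distinct, named error.
#'
#' @param ls A `bee_landscape`.
#' @return `ls`, invisibly.
#' @export
validate_landscape <- function(ls) {
  stopifnot(inherits(ls, "bee_landscape"))
  if (!identical(dim(ls$land_use), dim(ls$patch_id)))
    stop("raster shape mismatch: land_use and patch_id grids differ")
  codes <- unique(as.integer(ls$land_use))
  if (any(!codes %in% land_use_classes()))
    stop("unknown land-use code: ",
         paste(setdiff(codes, land_use_classes()), collapse = ", "))
  ids <- unique(as.integer(ls$patch_id))
  missing_ids <- setdiff(ids, ls$patch_table$patch_id)
  if (length(missing_ids) > 0)
    stop("patch id missing from table: ", paste(missing_ids, collapse = ", "))
  for (k in seq_len(nrow(ls$patch_table))) {
    pid <- ls$patch_table$patch_id[k]
    cells <- which(ls$patch_id == pid)
    if (length(cells) == 0) next
    if (length(cells) != ls$patch_table$area_cells[k])
      stop("patch area mismatch: patch ", pid, " covers ", length(cells),
           " cells but table says ", ls$patch_table$area_cells[k])
    lu <- unique(as.integer(ls$land_use)[cells])
    if (length(lu) != 1)
      stop("patch land-use mismatch: patch ", pid, " spans several classes")
    if (lu_name_of(lu) != ls$patch_table$land_use[k])
      stop("patch land-use mismatch: patch ", pid, " raster class disagrees",
           " with table")
  }
  if (any(ls$abz & ls$land_use != land_use_classes()["arable"]))
    stop("abz flag on non-arable cell")
  invisible(ls)
}

#' Number of cells of a landscape
#' @param ls A `bee_landscape`.
#' @return Integer cell count.
#' @export
n_cells <- function(ls) ls$n_rows * ls$n_cols

#' Landscape area in square meters
#' @param ls A `bee_landscape`.
#' @return Area in m^2.
#' @export
landscape_area_m2 <- function(ls) n_cells(ls) * ls$cell_size_m^2

#' @export
print.bee_landscape <- function(x, ...) {
  comp <- table(factor(lu_name_of(as.integer(x$land_use)), levels = lu_names()))
  cat("<bee_landscape> ", x$n_rows, "x", x$n_cols, " cells of ",
      x$cell_size_m, " m (", nrow(x$patch_table), " patches, ",
      sum(x$abz), " ABZ cells)\n", sep = "")
  print(round(comp / n_cells(x), 3))
  invisible(x)
}

# --- ESRI ASCII grid I/O ---------------------------------------------------

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop("ASCII grid body does not match header dimensions")
  # rows are written top-down, values row-major
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  attr(m, "header") <- hdr
  m
}

write_ascii_grid <- function(m, path, cellsize = 20, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", 0),
    paste("yllcorner", 0),
    paste("cellsize", cellsize),
    paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
}

#' Load a landscape from an ESRI ASCII raster and a patch table
#'
#' Reads a land-use raster (integer codes), its patch definition table (CSV
#' with columns `patch_id`, `land_use`, `area_cells`) and, when present, an
#' ABZ sidecar raster of 0/1 flags written by [write_landscape()]. The patch
#' id raster is taken from `<raster>_patches.asc` next to the land-use raster
#' if it exists, otherwise rebuilt by 4-connected component labelling.
#'
#' @param raster_path Path to the land-use `.asc` raster.
#' @param patch_table_path Path to the patch definition CSV.
#' @return A validated `bee_landscape`.
#' @export
load_landscape <- function(raster_path, patch_table_path) {
  m <- read_ascii_grid(raster_path)
  hdr <- attr(m, "header")
  storage.mode(m) <- "integer"
  pt <- read.csv(patch_table_path, stringsAsFactors = FALSE)
  need <- c("patch_id", "land_use", "area_cells")
  if (!all(need %in% names(pt)))
    stop("patch table must have columns ", paste(need, collapse = ", "))
  sidecar <- function(tag) sub("\\.asc$", paste0("_", tag, ".asc"), raster_path)
  pid <- NULL
  if (file.exists(sidecar("patches"))) {
    pid <- read_ascii_grid(sidecar("patches"))
    storage.mode(pid) <- "integer"
  }
  abz <- NULL
  if (file.exists(sidecar("abz"))) {
    abz <- read_ascii_grid(sidecar("abz")) != 0
  }
  cs <- if (!is.null(hdr$cellsize)) hdr$cellsize else 20
  landscape(m, patch_id = pid, patch_table = pt[need], cell_size_m = cs,
            abz = abz)
}

#' Write a landscape to ESRI ASCII rasters and a patch table
#'
#' Writes the land-use raster to `raster_path`, the patch-id raster to
#' `<raster>_patches.asc`, the ABZ layer (0/1) to `<raster>_abz.asc` and the
#' patch table to `patch_table_path`. [load_landscape()] on these files
#' reproduces the landscape cell for cell.
#'
#' @param ls A `bee_landscape`.
#' @param raster_path Output path for the land-use `.asc` raster.
#' @param patch_table_path Output path for the patch definition CSV.
#' @return `ls`, invisibly.
#' @export
write_landscape <- function(ls, raster_path, patch_table_path) {
  write_ascii_grid(ls$land_use, raster_path, cellsize = ls$cell_size_m)
  sidecar <- function(tag) sub("\\.asc$", paste0("_", tag, ".asc"), raster_path)
  write_ascii_grid(ls$patch_id, sidecar("patches"), cellsize = ls$cell_size_m)
  write_ascii_grid(ls$abz * 1L, sidecar("abz"), cellsize = ls$cell_size_m)
  write.csv(ls$patch_table, patch_table_path, row.names = FALSE)
  invisible(ls)
}

# --- ABZ selection ---------------------------------------------------------

#' Cells eligible for conversion to agricultural buffer zones
#'
#' An ABZ can only be placed on an arable cell directly bordering a grassland
#' or forest patch. Adjacency defaults to the 4-neighborhood (shared edge);
#' the 8-neighborhood is available for exploration.
#'
#' @param ls A `bee_landscape`.
#' @param adjacency 4 (default) or 8.
#' @return Two-column integer matrix of (row, col) coordinates, ordered by
#'   cell index (column-major), hence deterministic.
#' @export
potential_abz_cells <- function(ls, adjacency = 4) {
  lu <- ls$land_use
  target <- lu == land_use_classes()["forest"] |
    lu == land_use_classes()["grassland"]
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr
    cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (adjacency == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  near <- Reduce(`|`, lapply(offs, function(o) shift(target, o[1], o[2])))
  eligible <- lu == land_use_classes()["arable"] & near
  which(eligible, arr.ind = TRUE, useNames = FALSE)
}

#' Convert a fraction of the potential ABZ cells
#'
#' Flags `round-half-up(fraction * n_candidates)` eligible cells as ABZs.
#' Selection walks arable patches in descending area (ties by ascending patch
#' id), randomly permutes each patch's candidate cells, and exhausts a patch
#' before moving on to the next smaller one; `order = "ascending"` reverses
#' the patch order (sensitivity variant).
#'
#' @param ls A `bee_landscape`.
#' @param fraction Fraction of potential ABZ cells to convert, in `[0, 1]`.
#' @param order `"descending"` (default, largest arable patch first) or
#'   `"ascending"`.
#' @param adjacency Passed to [potential_abz_cells()].
#' @return A `bee_landscape` with the `abz` layer set. Uses the current RNG
#'   state for the within-patch permutations.
#' @export
apply_abz <- function(ls, fraction, order = c("descending", "ascending"),
                      adjacency = 4) {
  order <- match.arg(order)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  cand <- potential_abz_cells(ls, adjacency)
  n_sel <- round_half_up(fraction * nrow(cand))
  abz <- matrix(FALSE, ls$n_rows, ls$n_cols)
  if (n_sel > 0) {
    cand_idx <- (cand[, 2] - 1L) * ls$n_rows + cand[, 1]
    cand_patch <- as.integer(ls$patch_id)[cand_idx]
    pt <- ls$patch_table
    pt <- pt[pt$patch_id %in% cand_patch, , drop = FALSE]
    ord <- order(if (order == "descending") -pt$area_cells else pt$area_cells,
                 pt$patch_id)
    remaining <- n_sel
    for (pid in pt$patch_id[ord]) {
      in_patch <- cand_idx[cand_patch == pid]
      in_patch <- in_patch[sample.int(length(in_patch))]
      take <- min(remaining, length(in_patch))
      abz[in_patch[seq_len(take)]] <- TRUE
      remaining <- remaining - take
      if (remaining == 0) break
    }
  }
  ls$abz <- abz
  ls
}
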