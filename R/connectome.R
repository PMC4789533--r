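#' Parcellation of the tracking grid into labeled regions
#'
#' @param labels Integer 3D array; 0 is background, every nonzero value must
#'   appear in `region_table$region_id`.
#' @param region_table Data frame with columns `region_id` (unique positive
#'   integers), `region_name`, `hemisphere`; row order fixes the region order
#'   of every connectivity matrix built from this parcellation.
#' @return A `parcellation` object.
#' @export
parcellation <- function(labels, region_table) {
  region_table <- tibble::as_tibble(region_table)
  stopifnot(all(c("region_id", "region_name", "hemisphere") %in% names(region_table)))
  if (anyDuplicated(region_table$region_id)) stop_input("region ids must be unique")
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, region_table$region_id)
  if (length(missing) > 0L) {
    stop_input("label values not in the region table: %s", paste(missing, collapse = ", "))
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, region_table = region_table),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> grid %s, %d region(s), %d labeled voxel(s)\n",
              paste(dim(x$labels), collapse = " x "),
              nrow(x$region_table), sum(x$labels != 0)))
  invisible(x)
}

#' Motor-related region table (39 regions)
#'
#' The default parcellation table for cohort-level analyses: 19 bilateral
#' Desikan-Killiany-style motor-related regions (motor/premotor cortex,
#' dorsolateral prefrontal cortex, cingulate motor area, supplementary motor
#' area, parietal lobe, subcortical nuclei) plus the brainstem, 39 regions in
#' total. Region ids run 1..39 in the order left/right per structure, with
#' the brainstem last.
#'
#' @return A tibble with columns `region_id`, `region_name`, `hemisphere`,
#'   `cluster`.
#' @export
motor_regions <- function() {
  path <- system.file("extdata", "motor_regions.tsv", package = "factconn",
                      mustWork = TRUE)
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

streamline_terminal_voxels <- function(streamline) {
  vp <- streamline$voxel_path
  rbind(vp[1, ], vp[nrow(vp), ])
}

#' Assign a streamline's endpoints to parcellation regions
#'
#' Looks up the label of each terminal point's containing voxel and returns
#' the unordered region pair when both labels are nonzero and distinct;
#' otherwise `NULL` (an endpoint in background, or a self-loop within one
#' region, drops the fiber).
#'
#' @param streamline A `streamline`.
#' @param parcellation A [parcellation()] on the tracking grid.
#' @return Integer length-2 vector (sorted region ids) or `NULL`.
#' @export
assign_endpoints <- function(streamline, parcellation) {
  stopifnot(inherits(streamline, "streamline"), inherits(parcellation, "parcellation"))
  dims <- dim(parcellation$labels)
  ends <- streamline_terminal_voxels(streamline)
  for (r in 1:2) {
    if (!in_grid(ends[r, ], dims)) {
      stop_input("streamline endpoint voxel (%s) outside the parcellation grid",
                 paste(ends[r, ], collapse = ", "))
    }
  }
  a <- parcellation$labels[ends[1, 1], ends[1, 2], ends[1, 3]]
  b <- parcellation$labels[ends[2, 1], ends[2, 2], ends[2, 3]]
  if (a == 0L || b == 0L || a == b) return(NULL)
  sort(c(a, b))
}

#' Build an undirected fiber-count connectivity matrix
#'
#' Counts retained streamlines per unordered region pair (a streamline is
#' retained when [assign_endpoints()] maps both of its endpoints to distinct
#' regions), then zeroes entries with fewer than `min_fibers` fibers - sparse
#' connections are treated as tractography instability, with the boundary
#' count `min_fibers` itself retained. The result is symmetric with a zero
#' diagonal, rows/columns ordered by the parcellation's region table.
#'
#' @param streamlines An `fc_streamlines` (or plain list of `streamline`s).
#' @param parcellation A [parcellation()].
#' @param min_fibers Minimum retained fiber count per edge (default 5;
#'   entries with count < `min_fibers` are set to 0).
#' @return An integer region x region matrix of class `fc_connectivity`, with
#'   region names as dimnames and `min_fibers` attached as an attribute.
#' @export
build_connectivity_matrix <- function(streamlines, parcellation, min_fibers = 5L) {
  stopifnot(inherits(parcellation, "parcellation"), min_fibers >= 0)
  ids <- parcellation$region_table$region_id
  nR <- length(ids)
  W <- matrix(0L, nR, nR,
              dimnames = list(parcellation$region_table$region_name,
                              parcellation$region_table$region_name))
  pos <- match(seq_len(max(ids, 1L)), ids)   # region id -> matrix index
  for (s in streamlines) {
    pair <- assign_endpoints(s, parcellation)
    if (is.null(pair)) next
    i <- pos[pair[1]]
    j <- pos[pair[2]]
    W[i, j] <- W[i, j] + 1L
    W[j, i] <- W[j, i] + 1L
  }
  W[W < min_fibers] <- 0L
  structure(W, class = c("fc_connectivity", class(W)),
            min_fibers = as.integer(min_fibers))
}

#' @export
print.fc_connectivity <- function(x, ...) {
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("<fc_connectivity> %d x %d regions, %d nonzero edge(s), min_fibers = %d\n",
              nrow(x), ncol(x), nz, attr(x, "min_fibers") %||% NA_integer_))
  invisible(x)
}

#' Write / read a connectivity matrix as CSV
#'
#' Region names form the header row and first column, so per-subject CSVs are
#' directly comparable across subjects.
#'
#' @param matrix An `fc_connectivity` (or plain named square matrix).
#' @param path CSV file path.
#' @return `write_connectivity_csv()` returns `path` invisibly;
#'   `read_connectivity_csv()` returns an `fc_connectivity` matrix.
#' @export
write_connectivity_csv <- function(matrix, path) {
  df <- data.frame(region = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (!identical(rownames(m), colnames(m))) {
    stop_input("connectivity CSV row and column names differ")
  }
  structure(m, class = c("fc_connectivity", class(m)))
}
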