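#' Build a synthetic parcellation table
#'
#' Constructs a Power-atlas-style parcel table: contiguous region ids from
#' 0, one functional-network label per region, and deterministic synthetic
#' MNI-style coordinates on a 10 mm grid. Named networks are assigned first
#' in the order given; remaining regions are labeled `OTHER`.
#'
#' @param n_regions Total number of regions.
#' @param network_sizes Named integer vector of region counts per named
#'   network, e.g. `c(DMN = 58, SN = 18, FPN = 25)`. Each size must be at
#'   least 2 (a network needs two nodes for an efficiency to exist).
#' @return A data frame with columns `region_id`, `x`, `y`, `z`, `network`.
#' @export
#' @examples
#' make_parcel_table(10, c(DMN = 4, SN = 3, FPN = 3))
make_parcel_table <- function(n_regions,
                              network_sizes = c(DMN = 58, SN = 18, FPN = 25)) {
  if (n_regions < 2) stop("`n_regions` must be at least 2")
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes)))) {
    stop("`network_sizes` must be a named vector")
  }
  if (any(network_sizes < 2)) {
    bad <- names(network_sizes)[network_sizes < 2][1L]
    stop(sprintf("network '%s' must have at least 2 regions", bad))
  }
  cum <- cumsum(network_sizes)
  if (cum[length(cum)] > n_regions) {
    over <- names(network_sizes)[which(cum > n_regions)[1L]]
    stop(sprintf(
      "network sizes exceed n_regions = %d at network '%s' (total %d)",
      n_regions, over, sum(network_sizes)))
  }
  network <- rep("OTHER", n_regions)
  start <- 1L
  for (nm in names(network_sizes)) {
    network[start:(start + network_sizes[[nm]] - 1L)] <- nm
    start <- start + network_sizes[[nm]]
  }
  # deterministic coordinates: 10 mm lattice filling a cube, centered at 0
  side <- ceiling(n_regions^(1 / 3))
  idx <- arrayInd(seq_len(n_regions), rep(side, 3L))
  coords <- (idx - (side + 1) / 2) * 10
  data.frame(
    region_id = 0:(n_regions - 1L),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    network = network,
    stringsAsFactors = FALSE
  )
}

validate_parcel_table <- function(parcels) {
  req <- c("region_id", "x", "y", "z", "network")
  if (!is.data.frame(parcels) || !all(req %in% names(parcels))) {
    stop("parcel table must have columns: ", paste(req, collapse = ", "))
  }
  ids <- sort(parcels$region_id)
  if (anyDuplicated(ids) || !identical(as.integer(ids), 0:(nrow(parcels) - 1L))) {
    stop("region_ids must be unique and contiguous from 0")
  }
  tab <- table(parcels$network[parcels$network != "OTHER"])
  if (length(tab) && any(tab < 2)) {
    stop("every named network needs at least 2 regions; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  invisible(parcels)
}

#' Names of the named (non-OTHER) networks in a parcel table
#' @param parcels A parcel table from [make_parcel_table()].
#' @return Character vector of network names in order of first appearance.
#' @export
named_networks <- function(parcels) {
  validate_parcel_table(parcels)
  unique(parcels$network[parcels$network != "OTHER"])
}

#' @rdname make_parcel_table
#' @param parcels A parcel table.
#' @param path File path for the tab-separated table.
#' @export
write_parcel_table <- function(parcels, path) {
  validate_parcel_table(parcels)
  write_tsv(parcels, path)
}

#' @rdname make_parcel_table
#' @export
read_parcel_table <- function(path) {
  validate_parcel_table(read_tsv(path))
}
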