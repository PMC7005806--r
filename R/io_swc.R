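# SWC neuron morphology I/O. SWC is the standard 7-column text format for
# traced neurons: id, structure type, x, y, z (physical units), radius,
# parent id (-1 for the root). Comment lines start with '#' and are
# dropped on read (documented; round-trips preserve data, not comments).

#' Construct an SWC neuron from a node table
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Ids must be unique and every non-root parent must
#'   reference an existing id.
#' @return Object of class `SWCNeuron` with element `nodes`.
#' @export
swc_neuron <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("nodes must have columns ", paste(need, collapse = ", "))
  nodes <- as.data.frame(nodes)[need]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  dangling <- setdiff(nodes$parent, c(-1L, nodes$id))
  if (length(dangling))
    stop("dangling parent id(s): ", paste(dangling, collapse = ", "))
  if (!all(is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("non-finite coordinates")
  structure(list(nodes = nodes), class = "SWCNeuron")
}

#' Read an SWC file
#' @param path SWC text file.
#' @return [swc_neuron()] object.
#' @export
read_swc <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (length(ln) == 0L) stop("no nodes in ", path)
  fields <- lapply(ln, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (any(lengths(fields) != 7L))
    stop("SWC rows must have 7 columns: ", path)
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(m)) stop("non-numeric SWC entry in ", path)
  swc_neuron(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                        x = m[, 3], y = m[, 4], z = m[, 5],
                        radius = m[, 6], parent = as.integer(m[, 7])))
}

#' Write an SWC file
#'
#' Coordinates and radii are written with 6 decimal places.
#'
#' @param n [swc_neuron()].
#' @param path destination file.
#' @param header optional extra comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_swc <- function(n, path, header = character()) {
  stopifnot(inherits(n, "SWCNeuron"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# SWC: id type x y z radius parent",
    if (length(header)) paste("#", header)
  ), con)
  with(n$nodes, writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                                   id, type, x, y, z, radius, parent), con))
  invisible(path)
}

#' Topology fingerprint of an SWC neuron
#'
#' Hash of the (id, type, parent) table only; invariant under any spatial
#' transform of the coordinates.
#'
#' @param n [swc_neuron()].
#' @return character scalar.
#' @export
swc_topology_hash <- function(n) {
  s <- paste(n$nodes$id, n$nodes$type, n$nodes$parent, collapse = ";")
  as.character(sum(utf8ToInt(s) * seq_along(utf8ToInt(s)) %% 2147483647))
}
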