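#' Write a ground-truth arbor as SWC plus a JSON sidecar
#'
#' The morphology is written in the standard SWC format (one node per line:
#' `id type x y z radius parent`; type 1 = soma, 2 = axon). SWC carries no
#' kinetic fields, so per-branch conduction velocities and onsets go into a
#' JSON sidecar along with the node ranges needed for an exact round trip.
#'
#' @param arbor `axon_arbor`.
#' @param swc_path output SWC path.
#' @param json_path output JSON sidecar path.
#' @return invisibly, `swc_path`.
#' @export
write_ground_truth <- function(arbor, swc_path, json_path) {
  stopifnot(inherits(arbor, "axon_arbor"))
  nodes <- data.frame(id = 1L, type = 1L, x = arbor$soma[1L],
                      y = arbor$soma[2L], z = 0, radius = 5, parent = -1L)
  meta <- list()
  for (i in seq_along(arbor$branches)) {
    b <- arbor$branches[[i]]
    xy <- b$xy
    # attach to an existing node when the first vertex coincides with one
    d2 <- (nodes$x - xy[1L, 1L])^2 + (nodes$y - xy[1L, 2L])^2
    hit <- which(d2 < 1e-12)
    if (length(hit) > 0L) {
      parent0 <- hit[1L]
      xy <- xy[-1L, , drop = FALSE]
    } else {
      parent0 <- 1L  # rooted at the soma
    }
    first_id <- nrow(nodes) + 1L
    ids <- first_id + seq_len(nrow(xy)) - 1L
    nodes <- rbind(nodes, data.frame(
      id = ids, type = 2L, x = xy[, 1L], y = xy[, 2L], z = 0, radius = 0.5,
      parent = c(parent0, ids[-length(ids)])))
    meta[[i]] <- list(velocity = b$velocity, onset = b$onset,
                      first_node = first_id, n_nodes = nrow(xy))
  }
  lines <- sprintf("%d %d %.9g %.9g %.9g %.3g %d", nodes$id, nodes$type,
                   nodes$x, nodes$y, nodes$z, nodes$radius, nodes$parent)
  writeLines(c("# SWC ground-truth axonal arbor (synthetic)", lines),
             swc_path)
  jsonlite::write_json(list(soma = arbor$soma, seed = arbor$seed,
                            branches = meta),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(swc_path)
}

#' Read a ground-truth arbor back from SWC + sidecar
#'
#' @param swc_path SWC morphology path.
#' @param json_path JSON sidecar path written by [write_ground_truth()].
#' @return `axon_arbor` object.
#' @export
read_ground_truth <- function(swc_path, json_path) {
  swc <- read_swc(swc_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  soma <- as.numeric(meta$soma)
  branches <- lapply(seq_len(nrow(meta$branches)), function(i) {
    m <- meta$branches[i, ]
    ids <- m$first_node + seq_len(m$n_nodes) - 1L
    rows <- match(ids, swc$id)
    parent0 <- match(swc$parent[rows[1L]], swc$id)
    xy <- cbind(c(swc$x[parent0], swc$x[rows]),
                c(swc$y[parent0], swc$y[rows]))
    list(xy = xy, velocity = m$velocity, onset = m$onset)
  })
  structure(list(branches = branches, soma = soma, params = NULL,
                 seed = meta$seed),
            class = "axon_arbor")
}

#' Parse an SWC morphology file
#'
#' @param path SWC file.
#' @return data.frame with columns `id, type, x, y, z, radius, parent`.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                                  as.numeric))
  if (ncol(fields) != 7L) stop("malformed SWC file: ", path)
  data.frame(id = as.integer(fields[, 1L]), type = as.integer(fields[, 2L]),
             x = fields[, 3L], y = fields[, 4L], z = fields[, 5L],
             radius = fields[, 6L], parent = as.integer(fields[, 7L]))
}
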