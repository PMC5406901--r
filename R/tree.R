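#' Construct a single cell record
#'
#' A cell record holds the observable data of one cell in a lineage: its
#' position in the binary tree (generation `gen` and within-generation index
#' `idx`, 1-based), its lifetime, and a series of time-stamped fluorescence
#' readouts.  Times are on the cell-local clock that starts at 0 at birth;
#' division happens at `lifetime`.
#'
#' The mother of cell `(n, i)` is `(n - 1, ceiling(i / 2))` and its daughters
#' are `(n + 1, 2 i - 1)` and `(n + 1, 2 i)`.
#'
#' @param gen generation number, integer >= 0 (the founder cell has `gen = 0`).
#' @param idx within-generation index in `1..2^gen`.
#' @param lifetime cell lifetime in minutes, > 0.
#' @param obs_times strictly increasing observation times in `(0, lifetime]`
#'   (minutes, cell-local clock). May be empty.
#' @param readouts fluorescence readouts (arbitrary units), same length as
#'   `obs_times`.
#' @param latent optional latent-truth annotation attached by the simulator:
#'   a list with at least `type_path` (two-column matrix of time / discrete
#'   type), `D_div` and `F_div` (reporter concentrations at division).
#' @return a list of class `"cell_record"`.
#' @export
cell_record <- function(gen, idx, lifetime, obs_times = numeric(),
                        readouts = numeric(), latent = NULL) {
  gen <- as.integer(gen); idx <- as.integer(idx)
  obs_times <- as.numeric(obs_times); readouts <- as.numeric(readouts)
  if (gen < 0L) stop("cell (", gen, ",", idx, "): generation must be >= 0")
  if (idx < 1L || idx > 2^gen)
    stop("cell (", gen, ",", idx, "): index must lie in 1..2^gen")
  if (!is.finite(lifetime) || lifetime <= 0)
    stop("cell (", gen, ",", idx, "): lifetime must be positive")
  if (length(obs_times) != length(readouts))
    stop("cell (", gen, ",", idx, "): obs_times and readouts differ in length")
  if (length(obs_times) > 0) {
    if (any(diff(obs_times) <= 0))
      stop("cell (", gen, ",", idx, "): obs_times must be strictly increasing")
    if (obs_times[1] < 0 || obs_times[length(obs_times)] > lifetime + 1e-9)
      stop("cell (", gen, ",", idx, "): obs_times must lie in [0, lifetime]")
  }
  structure(list(gen = gen, idx = idx, lifetime = as.numeric(lifetime),
                 obs_times = obs_times, readouts = readouts, latent = latent),
            class = "cell_record")
}

#' @keywords internal
#' @noRd
cell_key <- function(gen, idx) paste0(gen, ".", idx)

#' Assemble a lineage tree from cell records
#'
#' A lineage tree is the full dataset of one tracked colony: a binary
#' genealogy rooted at cell `(0, 1)`, with per-cell lifetimes and readout
#' series.  The constructor validates the tree structure: the root must be
#' present, every non-root cell's mother must be present, and division is
#' binary (a mother with one daughter present must have both).
#'
#' @param cells a list of [cell_record()] objects.
#' @return a list of class `"lineage_tree"` with elements `cells` (named by
#'   `"gen.idx"`) and `n_generations`.
#' @seealso [read_tree()], [write_tree()], [subtree()], [simulate_tree()]
#' @export
lineage_tree <- function(cells) {
  if (length(cells) == 0) stop("a lineage tree needs at least the root cell")
  keys <- vapply(cells, function(cl) cell_key(cl$gen, cl$idx), "")
  if (anyDuplicated(keys))
    stop("duplicate cell id: (", keys[duplicated(keys)][1], ")")
  names(cells) <- keys
  if (!("0.1" %in% keys)) stop("missing root cell (0,1)")
  gens <- vapply(cells, `[[`, 0L, "gen")
  for (cl in cells) {
    if (cl$gen > 0L) {
      pk <- cell_key(cl$gen - 1L, ceiling(cl$idx / 2))
      if (!(pk %in% keys))
        stop("cell (", cl$gen, ",", cl$idx, "): parent (", pk, ") is missing")
    }
  }
  # binary division: one daughter present implies both present
  for (cl in cells) {
    k1 <- cell_key(cl$gen + 1L, 2L * cl$idx - 1L)
    k2 <- cell_key(cl$gen + 1L, 2L * cl$idx)
    if (xor(k1 %in% keys, k2 %in% keys))
      stop("cell (", cl$gen, ",", cl$idx,
           "): division is binary, exactly one daughter present")
  }
  has_latent <- vapply(cells, function(cl) !is.null(cl$latent), TRUE)
  if (any(has_latent) && !all(has_latent))
    stop("latent annotation must be present for all cells or none")
  # deterministic ordering: by generation, then index
  ord <- order(gens, vapply(cells, `[[`, 0L, "idx"))
  cells <- cells[ord]
  tr <- structure(list(cells = cells, n_generations = max(gens)),
                  class = "lineage_tree")
  tr$mothers <- compute_mothers(tr)
  tr
}

#' Number of cells in a lineage tree
#' @param tree a `lineage_tree`.
#' @return integer cell count.
#' @export
n_cells <- function(tree) length(tree$cells)

#' @export
print.lineage_tree <- function(x, ...) {
  nobs <- sum(vapply(x$cells, function(cl) length(cl$obs_times), 0L))
  cat("lineage tree: ", n_cells(x), " cells, ", x$n_generations + 1L,
      " generations (0..", x$n_generations, "), ", nobs, " readouts",
      if (!is.null(x$cells[[1]]$latent)) ", latent truth attached" else "",
      "\n", sep = "")
  invisible(x)
}

#' @keywords internal
#' @noRd
tree_has_latent <- function(tree) !is.null(tree$cells[[1]]$latent)

#' Mothers of a lineage tree that have daughters present
#'
#' @param tree a `lineage_tree`.
#' @return data.frame with columns `gen`, `idx` of each mother whose two
#'   daughters are in the tree, ordered by generation then index.
#' @keywords internal
#' @noRd
compute_mothers <- function(tree) {
  keys <- names(tree$cells)
  out <- list()
  for (cl in tree$cells) {
    if (cell_key(cl$gen + 1L, 2L * cl$idx) %in% keys)
      out[[length(out) + 1L]] <- c(cl$gen, cl$idx)
  }
  if (length(out) == 0)
    return(data.frame(gen = integer(), idx = integer()))
  m <- do.call(rbind, out)
  data.frame(gen = m[, 1], idx = m[, 2])
}

#' @keywords internal
#' @noRd
tree_mothers <- function(tree) {
  if (!is.null(tree$mothers)) tree$mothers else compute_mothers(tree)
}

#' Restrict a lineage tree to its first generations
#'
#' @param tree a `lineage_tree`.
#' @param max_generation keep cells with generation `<= max_generation`.
#' @return a `lineage_tree`.
#' @export
subtree <- function(tree, max_generation) {
  if (max_generation < 0 || max_generation > tree$n_generations)
    stop("max_generation must lie in 0..", tree$n_generations)
  keep <- Filter(function(cl) cl$gen <= max_generation, tree$cells)
  lineage_tree(unname(keep))
}

latent_to_json <- function(latent) {
  tp <- latent$type_path
  list(type_path = lapply(seq_len(nrow(tp)),
                          function(r) c(tp[r, 1], tp[r, 2])),
       D_div = latent$D_div, F_div = latent$F_div)
}

latent_from_json <- function(x) {
  tp <- do.call(rbind, lapply(x$type_path, as.numeric))
  colnames(tp) <- c("time", "type")
  list(type_path = tp, D_div = as.numeric(x$D_div),
       F_div = as.numeric(x$F_div))
}

#' Read a lineage tree from disk
#'
#' Two on-disk dialects are supported.  The JSON dialect is lossless:
#' `{"n_generations": N, "cells": [{"gen":, "idx":, "lifetime":,
#' "obs_times": [...], "readouts": [...], "latent": {...}}, ...]}` where the
#' optional latent block holds `type_path` (list of `[time, type]` pairs),
#' `D_div` and `F_div`.  The CSV dialect is a long table with columns
#' `gen,idx,lifetime,obs_time,readout`, one row per measurement (lifetime
#' repeated on each row); it carries no latent block and cannot represent
#' cells without readouts.
#'
#' @param path file to read.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return a validated [lineage_tree()].
#' @export
read_tree <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(doc$cells)) stop("malformed tree file: no 'cells' entry")
    cells <- lapply(doc$cells, function(cl) {
      for (f in c("gen", "idx", "lifetime"))
        if (is.null(cl[[f]]))
          stop("malformed cell record (missing '", f, "') in ", path)
      cell_record(cl$gen, cl$idx, cl$lifetime,
                  as.numeric(unlist(cl$obs_times)),
                  as.numeric(unlist(cl$readouts)),
                  latent = if (!is.null(cl$latent)) latent_from_json(cl$latent))
    })
    tr <- lineage_tree(cells)
    if (!is.null(doc$n_generations) &&
        as.integer(doc$n_generations) != tr$n_generations)
      stop("declared n_generations (", doc$n_generations,
           ") does not match the cells present (", tr$n_generations, ")")
    tr
  } else {
    d <- utils::read.csv(path)
    need <- c("gen", "idx", "lifetime", "obs_time", "readout")
    if (!all(need %in% names(d)))
      stop("csv tree file must have columns ", paste(need, collapse = ","))
    key <- paste0(d$gen, ".", d$idx)
    cells <- lapply(split(seq_len(nrow(d)), key), function(rows) {
      rows <- rows[order(d$obs_time[rows])]
      cell_record(d$gen[rows[1]], d$idx[rows[1]], d$lifetime[rows[1]],
                  d$obs_time[rows], d$readout[rows])
    })
    lineage_tree(unname(cells))
  }
}

#' Write a lineage tree to disk
#'
#' Inverse of [read_tree()]; see there for the dialects.  Latent annotation
#' is serialized in JSON only (the `type_path`/`D_div`/`F_div` block); extra
#' in-memory latent fields produced by the simulator are dropped.
#'
#' @param tree a `lineage_tree`.
#' @param path output file.
#' @param format `"json"` or `"csv"`; default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "json") {
    cells <- lapply(unname(tree$cells), function(cl) {
      rec <- list(gen = cl$gen, idx = cl$idx, lifetime = cl$lifetime,
                  obs_times = cl$obs_times, readouts = cl$readouts)
      if (!is.null(cl$latent)) rec$latent <- latent_to_json(cl$latent)
      rec
    })
    jsonlite::write_json(list(n_generations = tree$n_generations,
                              cells = cells),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    ks <- vapply(tree$cells, function(cl) length(cl$obs_times), 0L)
    if (any(ks == 0))
      stop("csv dialect cannot represent cells without readouts; use json")
    d <- do.call(rbind, lapply(unname(tree$cells), function(cl)
      data.frame(gen = cl$gen, idx = cl$idx, lifetime = cl$lifetime,
                 obs_time = cl$obs_times, readout = cl$readouts)))
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
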