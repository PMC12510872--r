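#' @name msn_tree
#' @title MSn fragmentation tree nodes
#'
#' @description A node of a precursor-lineage tree: all scans that share one
#' precursor lineage (several collision energies and repeat triggers),
#' plus child nodes one MS level deeper. The node's representative
#' precursor m/z is the TIC-weighted mean of its member scans' precursor
#' m/z values at the node's stage, which is stable under repeat triggers.
#' Nodes are plain lists of class `msn_tree` with fields `precursor_mz`,
#' `ms_level`, `scans`, `children`, `path` (representative m/z per stage
#' from the MS2 selection down) and `orphan`.
NULL

make_tree_node <- function(ms_level, scans, path, orphan = FALSE) {
  structure(list(
    precursor_mz = path[length(path)],
    ms_level = as.integer(ms_level),
    scans = scans,
    children = list(),
    path = as.numeric(path),
    orphan = isTRUE(orphan)
  ), class = "msn_tree")
}

# TIC-weighted representative of precursor m/z values
weighted_repr_mz <- function(mz, tic) {
  if (sum(tic) > 0) sum(mz * tic) / sum(tic) else mean(mz)
}

# Cluster sorted values by single-linkage with gap > tol as the break.
# Returns an integer group id per input value; deterministic and invariant
# to input order.
cluster_by_tol <- function(values, tol) {
  ord <- order(values)
  sorted <- values[ord]
  grp_sorted <- cumsum(c(1L, as.integer(diff(sorted) > tol)))
  grp <- integer(length(values))
  grp[ord] <- grp_sorted
  grp
}

#' Assemble MSn scans into precursor-lineage trees
#'
#' Groups the MS>=2 scans of one injection into a forest rooted at MS2
#' precursors. MS2 scans whose precursor m/z values agree within `mz_tol`
#' form one root; deeper scans attach to the node whose full path matches
#' their complete precursor chain within `mz_tol` at every stage, so
#' isobaric precursors at deeper levels cannot cross-link trees. Scans with
#' no matching parent become flagged single-node orphan trees.
#'
#' @param scans list of [msn_scan()] records from a single injection file
#'   (single polarity). MS1 scans are ignored here.
#' @param mz_tol chain-matching tolerance in Th (default 0.01; isolation
#'   windows are >= 1.2 Th so this is safely tight).
#' @return list of `msn_tree` roots (the forest), ordered by precursor m/z
#'   with orphan trees last.
#' @export
build_trees <- function(scans, mz_tol = 0.01) {
  msn <- Filter(function(s) s$ms_level >= 2L, scans)
  if (!length(msn)) return(list())

  orphans <- list()
  add_orphan <- function(scan) {
    path <- scan$precursor_chain$precursor_mz
    node <- make_tree_node(scan$ms_level, list(scan), path, orphan = TRUE)
    orphans[[length(orphans) + 1L]] <<- node
  }

  # grow a node at `ms_level` from member scans; `deeper` holds all scans of
  # the subtree at levels > ms_level (already matched to `path` prefix)
  grow <- function(ms_level, members, deeper, path) {
    members <- members[order(vapply(members, `[[`, integer(1L), "scan_number"))]
    repr <- weighted_repr_mz(
      vapply(members, function(s) s$precursor_chain$precursor_mz[ms_level - 1L],
             numeric(1L)),
      vapply(members, `[[`, numeric(1L), "tic"))
    path[length(path)] <- repr
    node <- make_tree_node(ms_level, members, path)

    nxt <- Filter(function(s) s$ms_level == ms_level + 1L, deeper)
    rest <- Filter(function(s) s$ms_level > ms_level + 1L, deeper)
    if (length(nxt)) {
      sel <- vapply(nxt, function(s) s$precursor_chain$precursor_mz[ms_level],
                    numeric(1L))
      grp <- cluster_by_tol(sel, mz_tol)
      reprs <- vapply(split(seq_along(nxt), grp), function(ix) {
        weighted_repr_mz(sel[ix], vapply(nxt[ix], `[[`, numeric(1L), "tic"))
      }, numeric(1L))
      # deeper-than-child scans follow the child whose representative m/z
      # matches their chain at this stage
      rest_assign <- rep(NA_integer_, length(rest))
      if (length(rest)) {
        rmz <- vapply(rest, function(s) s$precursor_chain$precursor_mz[ms_level],
                      numeric(1L))
        for (i in seq_along(rest)) {
          d <- abs(reprs - rmz[i])
          j <- which.min(d)
          if (d[j] <= mz_tol) rest_assign[i] <- j
        }
      }
      kids <- lapply(sort(unique(grp)), function(g) {
        grow(ms_level + 1L, nxt[grp == g],
             rest[!is.na(rest_assign) & rest_assign == g],
             c(path, reprs[[as.character(g)]]))
      })
      kids <- kids[order(vapply(kids, `[[`, numeric(1L), "precursor_mz"))]
      node$children <- kids
      for (s in rest[is.na(rest_assign)]) add_orphan(s)
    } else {
      for (s in rest) add_orphan(s)
    }
    node
  }

  ms2 <- Filter(function(s) s$ms_level == 2L, msn)
  deeper_all <- Filter(function(s) s$ms_level > 2L, msn)
  roots <- list()
  if (length(ms2)) {
    pmz <- vapply(ms2, function(s) s$precursor_chain$precursor_mz[1L], numeric(1L))
    grp <- cluster_by_tol(pmz, mz_tol)
    reprs <- vapply(split(seq_along(ms2), grp), function(ix) {
      weighted_repr_mz(pmz[ix], vapply(ms2[ix], `[[`, numeric(1L), "tic"))
    }, numeric(1L))
    assign_deep <- rep(NA_integer_, length(deeper_all))
    if (length(deeper_all)) {
      dmz <- vapply(deeper_all, function(s) s$precursor_chain$precursor_mz[1L],
                    numeric(1L))
      for (i in seq_along(deeper_all)) {
        d <- abs(reprs - dmz[i])
        j <- which.min(d)
        if (d[j] <= mz_tol) assign_deep[i] <- j
      }
    }
    roots <- lapply(sort(unique(grp)), function(g) {
      grow(2L, ms2[grp == g],
           deeper_all[!is.na(assign_deep) & assign_deep == g],
           reprs[[as.character(g)]])
    })
    for (s in deeper_all[is.na(assign_deep)]) add_orphan(s)
  } else {
    for (s in deeper_all) add_orphan(s)
  }

  roots <- roots[order(vapply(roots, `[[`, numeric(1L), "precursor_mz"))]
  if (length(orphans)) {
    okey <- order(vapply(orphans, `[[`, integer(1L), "ms_level"),
                  vapply(orphans, `[[`, numeric(1L), "precursor_mz"),
                  vapply(orphans, function(o) o$scans[[1L]]$scan_number,
                         integer(1L)))
    roots <- c(roots, orphans[okey])
  }
  roots
}

#' Select the best member scan at one collision energy
#'
#' Among a node's member scans acquired at `energy`, returns the one with
#' the highest TIC; TIC ties break to the earlier scan number. Returns
#' `NULL` when the node has no scan at that energy.
#'
#' @param node an [msn_tree] node.
#' @param energy collision energy in eV.
#' @param energy_tol numeric tolerance for energy equality.
#' @return an [msn_scan()] or `NULL`.
#' @export
select_best_scan <- function(node, energy, energy_tol = 1e-9) {
  stopifnot(inherits(node, "msn_tree"))
  at_energy <- Filter(function(s) {
    e <- scan_energy(s)
    !is.na(e) && abs(e - energy) <= energy_tol
  }, node$scans)
  if (!length(at_energy)) return(NULL)
  tics <- vapply(at_energy, `[[`, numeric(1L), "tic")
  sn <- vapply(at_energy, `[[`, integer(1L), "scan_number")
  at_energy[[order(-tics, sn)[1L]]]
}

node_energies <- function(node) {
  sort(unique(vapply(node$scans, scan_energy, numeric(1L))))
}

# flatten a tree into a list of nodes (preorder)
tree_nodes <- function(node) {
  c(list(node), unlist(lapply(node$children, tree_nodes), recursive = FALSE))
}

tree_depth <- function(node) {
  if (!length(node$children)) return(node$ms_level)
  max(vapply(node$children, tree_depth, numeric(1L)))
}

tree_scan_count <- function(node) {
  sum(vapply(tree_nodes(node), function(n) length(n$scans), integer(1L)))
}

#' @export
format.msn_tree <- function(x, indent = 0L, ...) {
  pad <- strrep("  ", indent)
  line <- sprintf(
    "%sMS%d m/z %.4f  [%d scan%s, energies %s]%s",
    pad, x$ms_level, x$precursor_mz, length(x$scans),
    if (length(x$scans) == 1L) "" else "s",
    paste(node_energies(x), collapse = "/"),
    if (x$orphan) "  (orphan)" else "")
  c(line, unlist(lapply(x$children, format.msn_tree, indent = indent + 1L)))
}

#' @export
print.msn_tree <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
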