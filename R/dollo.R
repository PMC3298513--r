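# Species-by-family presence matrices and Dollo-parsimony gain/loss
# reconstruction on a rooted species tree.

WASP_FAMILIES <- c("WASP", "WAVE", "WASH", "WHAMM", "WAWH", "WAML")

#' Build a species-by-family count matrix from classifications
#'
#' Counts classified records per species and family; unclassified records
#' are excluded, and pseudogene-flagged records are excluded by default.
#'
#' @param assignments Classification data frame (from
#'   [classify_proteome()]) with `id`, `species`, `family` and optionally
#'   `pseudogene` columns.
#' @param species_map Optional map (see [read_species_map()]) used to fill
#'   in missing species.
#' @param include_pseudogenes Count pseudogene-flagged records too.
#' @param families Column order of the result.
#' @return Integer matrix species x family.
#' @export
build_presence_matrix <- function(assignments, species_map = NULL,
                                  include_pseudogenes = FALSE,
                                  families = WASP_FAMILIES) {
  df <- assignments
  if (!is.null(species_map)) {
    i <- match(df$id, species_map$id)
    fill <- (is.na(df$species) | !nzchar(df$species)) & !is.na(i)
    df$species[fill] <- species_map$species[i[fill]]
  }
  df <- df[df$family %in% families, , drop = FALSE]
  missing <- is.na(df$species) | !nzchar(df$species)
  if (any(missing))
    stopf("species missing for record(s): %s",
          paste(df$id[missing], collapse = ", "))
  # The species set is the classified-species set, whether or not their
  # members survive the pseudogene filter.
  species <- sort(unique(df$species))
  if (!include_pseudogenes && "pseudogene" %in% names(df))
    df <- df[!isTRUE_vec(df$pseudogene), , drop = FALSE]
  mat <- matrix(0L, nrow = length(species), ncol = length(families),
                dimnames = list(species, families))
  if (nrow(df)) {
    tab <- table(factor(df$species, levels = species),
                 factor(df$family, levels = families))
    mat[] <- as.integer(tab)
  }
  mat
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# Ensure unique, non-empty node labels; returns the tree.
.label_nodes <- function(tree) {
  nn <- tree$Nnode
  if (is.null(tree$node.label) || length(tree$node.label) != nn)
    tree$node.label <- rep("", nn)
  blank <- !nzchar(tree$node.label) | is.na(tree$node.label)
  tree$node.label[blank] <- sprintf("N%d", which(blank) + length(tree$tip.label))
  tree
}

.node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node] else tree$node.label[node - ntip]
}

# children of each node, as a list indexed by node number
.children <- function(tree) {
  nmax <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", nmax)
  for (i in seq_len(nrow(tree$edge)))
    out[[tree$edge[i, 1L]]] <- c(out[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  out
}

# postorder list of node numbers (children before parents)
.postorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ch <- .children(tree)
  out <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    kids <- setdiff(ch[[v]], seen)
    if (length(kids) == 0L || v <= ntip) {
      out <- c(out, v)
      seen <- c(seen, v)
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, kids)
    }
  }
  out
}

#' Reconstruct per-family gain and loss events by Dollo parsimony
#'
#' For each family the single gain is placed on the edge above the most
#' recent common ancestor of all species carrying it; losses are the
#' maximal edges below the gain whose whole subtree lacks the family. This
#' single-gain, minimal-loss labelling formalises the presence/absence
#' narrative over the eukaryote tree. Tree tips absent from the matrix are
#' treated as "no data" (unsequenced, not lost) and never generate losses.
#'
#' @param tree A rooted `phylo` tree (ape). Unrooted trees are rooted at
#'   `outgroup` if given, otherwise at the midpoint, with a warning.
#' @param matrix Species x family count (or 0/1) matrix; every row name
#'   must be a tip of the tree.
#' @param outgroup Optional tip name used to root an unrooted input.
#' @return A `gain_loss_events` list: `events` data frame (family, edge =
#'   child-node name, event gain/loss), `states` (node x family implied
#'   presence), `tree` (the labelled, rooted tree) and `absent_families`
#'   (families with no presence anywhere).
#' @export
dollo_reconstruct <- function(tree, matrix, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    if (!is.null(outgroup)) {
      tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
      warnf("input tree was unrooted; rooted at outgroup '%s'", outgroup)
    } else if (requireNamespace("phangorn", quietly = TRUE)) {
      tree <- phangorn::midpoint(tree)
      warnf("input tree was unrooted; midpoint-rooted")
    } else {
      stopf("input tree is unrooted; supply an outgroup")
    }
  }
  tree <- .label_nodes(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  bad <- setdiff(rownames(matrix), tree$tip.label)
  if (length(bad)) stopf("matrix species not in tree: %s", paste(bad, collapse = ", "))

  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  po <- .postorder_nodes(tree)
  ch <- .children(tree)

  families <- colnames(matrix)
  nnode <- ntip + tree$Nnode
  states <- matrix(FALSE, nrow = nnode, ncol = length(families),
                   dimnames = list(vapply(seq_len(nnode), function(v)
                     .node_label(tree, v), ""), families))
  ev <- list()
  absent <- character(0)

  for (fam in families) {
    pres_tips <- intersect(rownames(matrix)[matrix[, fam] >= 1L], tree$tip.label)
    data_tips <- intersect(rownames(matrix), tree$tip.label)
    if (length(pres_tips) == 0L) {
      absent <- c(absent, fam)
      next
    }
    tipnum <- match(pres_tips, tree$tip.label)
    gain_node <- if (length(tipnum) == 1L) tipnum else ape::getMRCA(tree, tipnum)

    # per-node counts of present / absent data tips
    npres <- integer(nnode)
    nabs <- integer(nnode)
    datnum <- match(data_tips, tree$tip.label)
    npres[tipnum] <- 1L
    nabs[setdiff(datnum, tipnum)] <- 1L
    for (v in po) {
      if (v > ntip) {
        npres[v] <- sum(npres[ch[[v]]])
        nabs[v] <- sum(nabs[ch[[v]]])
      }
    }

    # in-gain-subtree flag
    in_gain <- logical(nnode)
    in_gain[gain_node] <- TRUE
    for (v in rev(po)) {
      if (v != gain_node && v != root && in_gain[parent[v]]) in_gain[v] <- TRUE
    }

    losses <- integer(0)
    for (v in seq_len(nnode)) {
      if (!in_gain[v] || v == gain_node) next
      if (npres[v] == 0L && nabs[v] >= 1L && npres[parent[v]] > 0L)
        losses <- c(losses, v)
    }

    # implied presence states
    under_loss <- logical(nnode)
    for (v in rev(po)) {
      if (v %in% losses) under_loss[v] <- TRUE
      else if (v != root && under_loss[parent[v]]) under_loss[v] <- TRUE
    }
    states[, fam] <- in_gain & !under_loss

    ev[[fam]] <- data.frame(
      family = fam,
      edge = c(.node_label(tree, gain_node),
               vapply(losses, function(v) .node_label(tree, v), "")),
      event = c("gain", rep("loss", length(losses))),
      stringsAsFactors = FALSE)
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(family = character(), edge = character(), event = character(),
               stringsAsFactors = FALSE)
  rownames(events) <- NULL
  structure(list(events = events, states = states, tree = tree,
                 absent_families = absent),
            class = "gain_loss_events")
}

#' @export
print.gain_loss_events <- function(x, ...) {
  cat(sprintf("<gain_loss_events> %d events over %d families\n",
              nrow(x$events), length(unique(x$events$family))))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Collapse the tree into clades with a uniform family inventory
#'
#' Walks the tree top-down and reports each maximal clade whose species all
#' share an identical row of the presence matrix, together with the
#' reconstructed event list rendered as text.
#'
#' @param matrix Species x family count matrix.
#' @param tree Rooted `phylo` tree covering the matrix species.
#' @param events Optional [dollo_reconstruct()] result to render.
#' @return List with `inventory` (data frame: taxon, n_species, one column
#'   per family) and `events_text` (character vector).
#' @export
summarize_inventory <- function(matrix, tree, events = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tree <- .label_nodes(tree)
  ntip <- length(tree$tip.label)
  ch <- .children(tree)
  rows <- apply(matrix, 1L, paste, collapse = ",")

  tips_under <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(ch[[v]], tips_under))
  }
  uniform <- function(v) {
    sp <- intersect(tree$tip.label[tips_under(v)], rownames(matrix))
    if (length(sp) == 0L) return(NULL)
    if (length(unique(rows[sp])) == 1L) sp else NULL
  }
  out <- list()
  walk <- function(v) {
    sp <- uniform(v)
    if (!is.null(sp)) {
      out[[length(out) + 1L]] <<- data.frame(
        taxon = .node_label(tree, v), n_species = length(sp),
        as.data.frame(t(matrix[sp[1L], , drop = TRUE])),
        stringsAsFactors = FALSE)
    } else if (v > ntip) {
      for (k in ch[[v]]) walk(k)
    }
  }
  walk(ntip + 1L)
  inventory <- if (length(out)) do.call(rbind, out) else
    data.frame(taxon = character(), n_species = integer())
  rownames(inventory) <- NULL
  events_text <- character(0)
  if (!is.null(events) && nrow(events$events)) {
    events_text <- sprintf("%s: %s on edge above %s", events$events$family,
                           events$events$event, events$events$edge)
  }
  list(inventory = inventory, events_text = events_text)
}
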