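# state ordering used for deterministic tie-breaking: bases first, then gap
STATE_ORDER <- c("A", "C", "G", "T", "-")

state_min <- function(states) STATE_ORDER[min(match(states, STATE_ORDER))]

# bit encoding of the five states, in tie-break order
STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L)

# lowest set bit of each element (deterministic tie-break: A < C < G < T < -)
lowest_bit <- function(b) bitwXor(b, bitwAnd(b, b - 1L))

bits_to_state <- function(bits) STATE_ORDER[match(bits, STATE_BITS)]

# per-species majority state and allele-set bitmask at every column
# (vectorised; 'N' is missing, an all-missing column becomes a gap)
species_column_states <- function(aln, species = NULL) {
  sp <- species %||% alignment_species(aln)
  L <- aln$length
  states <- matrix("-", nrow = length(sp), ncol = L, dimnames = list(sp, NULL))
  set_bits <- matrix(16L, nrow = length(sp), ncol = L, dimnames = list(sp, NULL))
  for (s in sp) {
    mat <- aln$mat[aln$species == s, , drop = FALSE]
    counts <- vapply(STATE_ORDER, function(st) colSums(mat == st),
                     numeric(L))                     # L x 5
    if (L == 1L) counts <- matrix(counts, nrow = 1L)
    present <- counts > 0
    bits <- as.integer(present %*% STATE_BITS)
    maj <- max.col(counts, ties.method = "first")    # first = STATE_ORDER
    empty <- rowSums(counts) == 0
    bits[empty] <- 16L; maj[empty] <- 5L
    set_bits[s, ] <- bits
    states[s, ] <- STATE_ORDER[maj]
  }
  list(states = states, set_bits = set_bits)
}

# children lookup and postorder for an ape tree; nodes are labelled:
# tips keep their species label, internal nodes become "node<k>"
tree_scaffold <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- c(tree$tip.label, paste0("node", (ntip + 1L):nnode))
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1L]]] <- c(children[[tree$edge[e, 1L]]],
                                      tree$edge[e, 2L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  post <- integer(0)
  stack <- root; seen <- logical(nnode)
  # iterative postorder
  order_stack <- integer(0)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_stack <- c(order_stack, nd)
    stack <- c(stack, children[[nd]])
  }
  post <- rev(order_stack)
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  list(ntip = ntip, nnode = nnode, labels = labels, children = children,
       root = root, postorder = post, preorder = order_stack, parent = parent)
}

# Fitch parsimony, vectorised over all columns with bitmask state sets.
# leaf_bits: ntip x L integer matrix.  Returns per-node resolved state bits
# (nnode x L) and the per-column parsimony change count.
fitch_all_columns <- function(sc, leaf_bits) {
  L <- ncol(leaf_bits)
  sets <- matrix(0L, nrow = sc$nnode, ncol = L)
  sets[seq_len(sc$ntip), ] <- leaf_bits
  score <- integer(L)
  for (nd in sc$postorder) {
    kids <- sc$children[[nd]]
    if (length(kids) == 0L) next
    cur <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(cur, sets[k, ])
      miss <- inter == 0L
      score <- score + miss
      cur <- ifelse(miss, bitwOr(cur, sets[k, ]), inter)
    }
    sets[nd, ] <- cur
  }
  states <- matrix(0L, nrow = sc$nnode, ncol = L)
  for (nd in sc$preorder) {
    p <- sc$parent[nd]
    if (is.na(p)) states[nd, ] <- lowest_bit(sets[nd, ])
    else {
      keep <- bitwAnd(states[p, ], sets[nd, ]) > 0L
      states[nd, ] <- ifelse(keep, states[p, ], lowest_bit(sets[nd, ]))
    }
  }
  list(state_bits = states, score = score, set_bits = sets)
}

#' Parsimony reconstruction of ancestral sequences
#'
#' Runs Fitch parsimony column by column over the species tree, using each
#' species' allele set as its leaf state (so a polymorphic species can agree
#' with either neighbour: a column where two species' allele sets overlap is
#' never forced to carry a fixed difference).  Gaps are carried as a fifth
#' state so internal-node sequences have a well-defined gap pattern; ties are
#' resolved deterministically (shared child state, then alphabetical).
#'
#' @param aln a `haplotype_alignment` (ingroup only).
#' @param tree an [ape::phylo] whose tips cover the alignment species.
#' @return list with `node_seqs` (named character vector of full-length
#'   sequences for every tip and internal node), `scaffold`, and
#'   `parsimony_score` (per-column integer vector of state changes).
#' @export
reconstruct_ancestral <- function(aln, tree) {
  validate_tree_alignment(aln, tree)
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, alignment_species(aln)))
  sc <- tree_scaffold(tree)
  st <- species_column_states(aln)
  fc <- fitch_all_columns(sc, st$set_bits[tree$tip.label, , drop = FALSE])
  seqs <- matrix(bits_to_state(fc$state_bits), nrow = sc$nnode)
  score <- fc$score
  node_seqs <- apply(seqs, 1L, paste, collapse = "")
  names(node_seqs) <- sc$labels
  list(node_seqs = node_seqs, scaffold = sc, tree = tree,
       parsimony_score = score, species_states = st)
}

#' Fixed substitutions mapped to tree branches
#'
#' A fixed substitution is a parent/child state difference (both states
#' bases) on a branch of the parsimony reconstruction, at a column free of
#' gaps and missing data in every ingroup haplotype.  Columns where a
#' species is polymorphic contribute that species' allele set, so overlap
#' with a neighbour suppresses a spurious fixed difference (treated as
#' ancestral polymorphism subsequently fixed).
#'
#' @inheritParams reconstruct_ancestral
#' @param recon optional result of [reconstruct_ancestral()] to reuse.
#' @return data.frame of events: `column` (0-based), `kind` (`"fixed"`),
#'   `branch` (label of the child node of the branch), `parent`, `from`,
#'   `to`, `count` (1).
#' @export
infer_fixed_substitutions <- function(aln, tree, recon = NULL) {
  if (is.null(recon)) recon <- reconstruct_ancestral(aln, tree)
  sc <- recon$scaffold
  clean <- complete_deletion_sites(aln) + 1L
  seqm <- do.call(rbind, strsplit(recon$node_seqs, ""))
  rownames(seqm) <- names(recon$node_seqs)
  ev <- list()
  for (nd in seq_len(sc$nnode)) {
    p <- sc$parent[nd]
    if (is.na(p)) next
    pj <- seqm[sc$labels[p], ]; cj <- seqm[sc$labels[nd], ]
    idx <- clean[pj[clean] != cj[clean] &
                 pj[clean] %in% c("A", "C", "G", "T") &
                 cj[clean] %in% c("A", "C", "G", "T")]
    if (length(idx))
      ev[[length(ev) + 1L]] <- data.frame(
        column = idx - 1L, kind = "fixed", branch = sc$labels[nd],
        parent = sc$labels[p], species = NA_character_,
        from = pj[idx], to = cj[idx], count = 1L)
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(column = integer(), kind = character(), branch = character(),
                  parent = character(), species = character(),
                  from = character(), to = character(), count = integer())
}

#' Within-species polymorphic substitutions
#'
#' One event per extra allele per segregating column per species, with the
#' species' majority allele as the reference state.  With the singleton
#' filter on, variants carried by exactly one haplotype are flagged as not
#' counted (they are retained in the catalog for auditability), except for
#' species in `exempt` - the concession made for species represented by a
#' single line whose removal would discard all information.
#'
#' @param aln a `haplotype_alignment`.
#' @param species species to scan (default all).
#' @param singleton_filter drop single-carrier variants (default `TRUE`).
#' @param exempt species exempt from the singleton filter.
#' @return data.frame of events with the same columns as
#'   [infer_fixed_substitutions()] plus `counted`.
#' @export
collect_polymorphisms <- function(aln, species = NULL, singleton_filter = TRUE,
                                  exempt = character()) {
  sp <- species %||% alignment_species(aln)
  clean <- complete_deletion_sites(aln) + 1L
  ev <- list()
  for (s in sp) {
    mat <- aln$mat[aln$species == s, , drop = FALSE]
    for (j in clean) {
      tab <- table(mat[, j])
      if (length(tab) < 2L) next
      cand <- names(tab)[tab == max(tab)]
      major <- state_min(cand)
      for (allele in setdiff(names(tab), major)) {
        counted <- !(singleton_filter && tab[[allele]] == 1L && !(s %in% exempt))
        ev[[length(ev) + 1L]] <- data.frame(
          column = j - 1L, kind = "polymorphic", branch = NA_character_,
          parent = NA_character_, species = s, from = major, to = allele,
          count = as.integer(tab[[allele]]), counted = counted)
      }
    }
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(column = integer(), kind = character(), branch = character(),
                  parent = character(), species = character(),
                  from = character(), to = character(), count = integer(),
                  counted = logical())
}

# scan an ungapped view of a full-length (possibly gapped) sequence and
# return the hit intervals lifted to the column frame
scan_sequence_sites <- function(seq_full, method, library,
                                core_cut = 1, overall_cut = 0.7) {
  chars <- strsplit(seq_full, "")[[1L]]
  base_cols <- which(chars %in% c("A", "C", "G", "T"))
  empty <- data.frame(start = integer(), end = integer(), factor = character())
  if (length(base_cols) == 0L) return(empty)
  ungapped <- paste(chars[base_cols], collapse = "")
  tr <- switch(method,
    PATCH = patch_scan(ungapped, library),
    MATCH = match_scan(ungapped, library, core_cut, overall_cut),
    MATCH_CORE = core_only_track(match_scan(ungapped, library, core_cut, overall_cut)),
    stop("unsupported per-sequence scan method: ", method))
  iv <- tr$intervals
  if (nrow(iv) == 0L) return(empty)
  data.frame(start = base_cols[iv$start + 1L] - 1L,
             end = base_cols[iv$end],
             factor = iv$factor)
}

# does any interval of `sites` overlap 0-based column?
sites_overlapping <- function(sites, column) {
  sites[sites$start <= column & column < sites$end, , drop = FALSE]
}

site_keys <- function(sites) paste(sites$start, sites$end, sites$factor)

#' Classify the binding-site effect of one substitution
#'
#' A base change affects a TFBS if it falls in a stretch annotated as a site
#' either before or after the change.  `gain`: the change creates a site
#' absent before; `loss`: it destroys a site present before; `change`: a
#' site is destroyed and another created at the position (one site converted
#' into another); `in_site`: the position is inside a site that exists both
#' before and after; `none`: outside any site in both states.
#'
#' @param column 0-based column of the event.
#' @param sites_before,sites_after data.frames (`start`, `end`, `factor`, on
#'   the column frame) annotating the sequence before and after the change.
#' @return one of `"gain"`, `"loss"`, `"change"`, `"in_site"`, `"none"`.
#' @export
classify_tfbs_effect <- function(column, sites_before, sites_after) {
  kb <- site_keys(sites_before); ka <- site_keys(sites_after)
  lost <- sites_before[!(kb %in% ka), , drop = FALSE]
  gained <- sites_after[!(ka %in% kb), , drop = FALSE]
  lost_ov <- nrow(sites_overlapping(lost, column)) > 0L
  gained_ov <- nrow(sites_overlapping(gained, column)) > 0L
  if (lost_ov && gained_ov) return("change")
  if (gained_ov) return("gain")
  if (lost_ov) return("loss")
  stable <- sites_before[kb %in% ka, , drop = FALSE]
  if (nrow(sites_overlapping(stable, column)) > 0L) return("in_site")
  "none"
}

#' Chronology rule for multi-hit binding-site turnover
#'
#' When several substitutions on one branch eliminate the same pre-existing
#' site, only the chronologically first (leftmost column, a stated
#' convention: the true order within a branch is unknowable) is counted as
#' the loss; when several jointly form a new site, only the last is counted
#' as the gain.  All events remain in the catalog; the rule only toggles
#' their `counted` flag for the turnover tallies.
#'
#' @param events data.frame of fixed events with `column`, `branch`, `effect`.
#' @param lost_sites,gained_sites lists (indexed by branch label) of site
#'   data.frames destroyed / created on that branch.
#' @return the events with a logical `counted` column.
#' @export
apply_chronology_rule <- function(events, lost_sites, gained_sites) {
  counted <- rep(NA, nrow(events))
  mark <- function(idx, keep_idx) {
    for (i in idx) counted[i] <<- isTRUE(counted[i]) || i == keep_idx
    counted[keep_idx] <<- TRUE
  }
  for (br in unique(events$branch)) {
    onb <- which(events$branch == br)
    for (st in seq_len(nrow(lost_sites[[br]] %||% data.frame()))) {
      s <- lost_sites[[br]][st, ]
      idx <- onb[events$effect[onb] %in% c("loss", "change") &
                 events$column[onb] >= s$start & events$column[onb] < s$end]
      if (length(idx) > 1L) mark(idx, idx[which.min(events$column[idx])])
    }
    for (st in seq_len(nrow(gained_sites[[br]] %||% data.frame()))) {
      s <- gained_sites[[br]][st, ]
      idx <- onb[events$effect[onb] %in% c("gain", "change") &
                 events$column[onb] >= s$start & events$column[onb] < s$end]
      if (length(idx) > 1L) mark(idx, idx[which.max(events$column[idx])])
    }
  }
  events$counted <- ifelse(is.na(counted), TRUE, counted)
  events
}

#' Per-species TFBS base fraction and its cross-species average
#'
#' For per-sequence scan methods the fraction is the share of a species'
#' ungapped bases covered by the union mask of its own scan; for static
#' column tracks it is the share of the species' bases lying at covered
#' columns.  The unweighted mean across species is the fraction used by the
#' composition and equilibrium-rate estimators.
#'
#' @param per_species_sites list (by species) of site data.frames on the
#'   column frame.
#' @param species_seqs named character vector of full-length species
#'   sequences (majority states).
#' @return list with `per_species` (named numeric) and `mean`.
#' @export
tfbs_base_fraction <- function(per_species_sites, species_seqs) {
  frac <- vapply(names(species_seqs), function(s) {
    chars <- strsplit(species_seqs[[s]], "")[[1L]]
    base_cols <- which(chars %in% c("A", "C", "G", "T"))
    if (length(base_cols) == 0L) return(NA_real_)
    sites <- per_species_sites[[s]]
    mask <- logical(length(chars))
    for (k in seq_len(nrow(sites)))
      mask[(sites$start[k] + 1L):sites$end[k]] <- TRUE
    mean(mask[base_cols])
  }, 0)
  list(per_species = frac, mean = mean(frac, na.rm = TRUE))
}

#' Build the full substitution catalog for one annotation method
#'
#' Identifies fixed (parsimony-mapped) and polymorphic substitutions,
#' classifies every event against the method's binding-site annotation of
#' the relevant sequence before and after the change, applies the singleton
#' filter and the chronology rule, and tallies the totals that feed the
#' McDonald-Kreitman and rate estimators.
#'
#' For `PATCH`, `MATCH`, `MATCH_CORE` and `COMBINED` the annotation is
#' recomputed by scanning each reconstructed ancestral and derived sequence;
#' for `DNASE`, `PHYLO` and `TRUTH` a fixed column-frame track is used and
#' events are classified as `in_site`/`none` by mask membership.
#'
#' @param aln ingroup `haplotype_alignment`.
#' @param tree species tree ([ape::phylo]).
#' @param method one of `PATCH, MATCH, MATCH_CORE, COMBINED, DNASE, PHYLO, TRUTH`.
#' @param library `motif_library` (scan methods).
#' @param static_track `annotation_track` on alignment columns (static methods).
#' @param singleton_filter,exempt see [collect_polymorphisms()].
#' @param overall_cut overall-similarity cutoff passed to [match_scan()].
#' @return object of class `substitution_catalog`: list with `events`,
#'   `totals` (kind x effect table of counted events), `base_fraction`,
#'   `method`, `recon`.
#' @export
build_catalog <- function(aln, tree, method, library = NULL,
                          static_track = NULL, singleton_filter = TRUE,
                          exempt = character(), overall_cut = 0.7) {
  method <- match.arg(method, TRACK_METHODS)
  scan_based <- method %in% c("PATCH", "MATCH", "MATCH_CORE", "COMBINED")
  if (scan_based && is.null(library)) stop("scan method needs a motif library")
  if (!scan_based && is.null(static_track)) stop("static method needs a track")
  recon <- reconstruct_ancestral(aln, tree)
  sc <- recon$scaffold
  sp <- alignment_species(aln)
  species_seqs <- recon$node_seqs[sp]

  node_sites <- NULL
  static_sites <- NULL
  if (scan_based) {
    scan1 <- function(seq_full) {
      if (method == "COMBINED") {
        rbind(scan_sequence_sites(seq_full, "PATCH", library),
              scan_sequence_sites(seq_full, "MATCH", library,
                                  overall_cut = overall_cut))
      } else scan_sequence_sites(seq_full, method, library,
                                 overall_cut = overall_cut)
    }
    node_sites <- lapply(recon$node_seqs, scan1)
  } else {
    iv <- static_track$intervals
    static_sites <- data.frame(start = iv$start, end = iv$end, factor = iv$factor)
  }

  fixed <- infer_fixed_substitutions(aln, tree, recon)
  poly <- collect_polymorphisms(aln, singleton_filter = singleton_filter,
                                exempt = exempt)

  # classify fixed events
  if (nrow(fixed)) {
    fixed$effect <- vapply(seq_len(nrow(fixed)), function(i) {
      if (scan_based)
        classify_tfbs_effect(fixed$column[i],
                             node_sites[[fixed$parent[i]]],
                             node_sites[[fixed$branch[i]]])
      else {
        ov <- nrow(sites_overlapping(static_sites, fixed$column[i])) > 0L
        if (ov) "in_site" else "none"
      }
    }, "")
  } else fixed$effect <- character()

  # chronology rule on fixed events (scan methods only; static sites never turn over)
  if (scan_based && nrow(fixed)) {
    lost <- list(); gained <- list()
    for (nd in seq_len(sc$nnode)) {
      p <- sc$parent[nd]
      if (is.na(p)) next
      before <- node_sites[[sc$labels[p]]]; after <- node_sites[[sc$labels[nd]]]
      kb <- site_keys(before); ka <- site_keys(after)
      lost[[sc$labels[nd]]] <- before[!(kb %in% ka), , drop = FALSE]
      gained[[sc$labels[nd]]] <- after[!(ka %in% kb), , drop = FALSE]
    }
    fixed <- apply_chronology_rule(fixed, lost, gained)
  } else fixed$counted <- rep(TRUE, nrow(fixed))

  # classify polymorphic events against the species' own annotation
  if (nrow(poly)) {
    poly$effect <- vapply(seq_len(nrow(poly)), function(i) {
      s <- poly$species[i]
      if (scan_based) {
        before <- node_sites[[s]]
        chars <- strsplit(species_seqs[[s]], "")[[1L]]
        chars[poly$column[i] + 1L] <- poly$to[i]
        after <- if (method == "COMBINED") {
          rbind(scan_sequence_sites(paste(chars, collapse = ""), "PATCH", library),
                scan_sequence_sites(paste(chars, collapse = ""), "MATCH", library,
                                    overall_cut = overall_cut))
        } else scan_sequence_sites(paste(chars, collapse = ""), method, library,
                                   overall_cut = overall_cut)
        classify_tfbs_effect(poly$column[i], before, after)
      } else {
        ov <- nrow(sites_overlapping(static_sites, poly$column[i])) > 0L
        if (ov) "in_site" else "none"
      }
    }, "")
  } else poly$effect <- character()

  events <- rbind(fixed[, c("column", "kind", "branch", "parent", "species",
                            "from", "to", "count", "effect", "counted")],
                  poly[, c("column", "kind", "branch", "parent", "species",
                           "from", "to", "count", "effect", "counted")])
  rownames(events) <- NULL

  # base fractions
  if (scan_based) {
    bf <- tfbs_base_fraction(node_sites[sp], species_seqs)
  } else {
    per_sp <- lapply(sp, function(s) static_sites); names(per_sp) <- sp
    bf <- tfbs_base_fraction(per_sp, species_seqs)
  }

  counted <- events[events$counted, , drop = FALSE]
  effects <- c("none", "gain", "loss", "change", "in_site")
  totals <- table(factor(counted$kind, c("fixed", "polymorphic")),
                  factor(counted$effect, effects))
  structure(list(events = events, totals = totals, base_fraction = bf,
                 method = method, recon = recon),
            class = "substitution_catalog")
}

#' @export
print.substitution_catalog <- function(x, ...) {
  cat("substitution_catalog [", x$method, "]: ", nrow(x$events), " events (",
      sum(x$events$counted), " counted), mean TFBS base fraction ",
      round(x$base_fraction$mean, 4), "\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' 2x2 McDonald-Kreitman counts from a catalog
#'
#' Fixed and polymorphic counted events are split into the TFBS class
#' (effect other than `none`) and the NTFBS class (effect `none`).
#'
#' @param catalog a `substitution_catalog`.
#' @return an `mk_table` (see [mk_table()]).
#' @export
catalog_mk_table <- function(catalog) {
  ev <- catalog$events[catalog$events$counted, , drop = FALSE]
  tf <- ev$effect != "none"
  fx <- ev$kind == "fixed"
  mk_table(fixed_tfbs = sum(fx & tf), fixed_ntfbs = sum(fx & !tf),
           poly_tfbs = sum(!fx & tf), poly_ntfbs = sum(!fx & !tf),
           method_label = catalog$method)
}

#' Write a substitution catalog to TSV (1-based columns)
#' @param catalog a `substitution_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  ev <- catalog$events
  ev$column <- ev$column + 1L
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
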