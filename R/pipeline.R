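#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one alignment: per-species diversity
#' summaries, the conservation profile, the requested TFBS annotation
#' methods, substitution catalogs, McDonald-Kreitman tables and the
#' relative-rate estimators, writing one TSV per report into `out_dir`
#' together with a JSON run manifest.  Reruns with the same inputs are
#' byte-identical (no timestamps in outputs).
#'
#' @param aln a `haplotype_alignment` (may include the outgroup).
#' @param tree species tree covering the ingroup species (and the outgroup
#'   if `outgroup_species` is given).
#' @param out_dir output directory.
#' @param methods annotation methods to run; subset of
#'   `PATCH, MATCH, MATCH_CORE, COMBINED, DNASE, PHYLO`.
#' @param library `motif_library` for the scan methods.
#' @param dnase_track optional `annotation_track` (alignment columns) with
#'   DNase-I footprints; required for method `DNASE`.
#' @param outgroup_species species id of the outgroup (required for `PHYLO`;
#'   its haplotypes are excluded from all ingroup statistics).
#' @param singleton_filter,exempt see [collect_polymorphisms()].
#' @param window conservation smoothing window.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(aln, tree, out_dir,
                         methods = c("PATCH", "MATCH"),
                         library = toy_motif_library(),
                         dnase_track = NULL, outgroup_species = NULL,
                         singleton_filter = TRUE, exempt = character(),
                         window = 11L) {
  methods <- match.arg(methods, c("PATCH", "MATCH", "MATCH_CORE", "COMBINED",
                                  "DNASE", "PHYLO"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ingroup <- aln
  if (!is.null(outgroup_species))
    ingroup <- subset_species(aln, setdiff(alignment_species(aln),
                                           outgroup_species))
  ingroup_tree <- ape::drop.tip(tree, setdiff(tree$tip.label,
                                              alignment_species(ingroup)))

  # stage: diversity (per species with >= 2 haplotypes)
  div <- do.call(rbind, lapply(alignment_species(ingroup), function(s) {
    if (sum(ingroup$species == s) < 2L) return(NULL)
    diversity_summary(ingroup, s)
  }))
  if (!is.null(div)) {
    div_out <- div
    div_out$pi_e3 <- div_out$pi * 1e3
    div_out$theta_e3 <- div_out$theta_w * 1e3
    utils::write.table(div_out, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }

  # stage: conservation profile
  prof <- conservation_profile(ingroup, window = window)
  utils::write.table(prof, file.path(out_dir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  # stage: annotation + catalog + tests per method
  catalogs <- list(); mk_rows <- list(); rate_rows <- list()
  for (m in methods) {
    cat_m <- switch(m,
      DNASE = {
        if (is.null(dnase_track)) stop("stage scan[DNASE]: no DNase track supplied")
        build_catalog(ingroup, ingroup_tree, "DNASE", static_track = dnase_track,
                      singleton_filter = singleton_filter, exempt = exempt)
      },
      PHYLO = {
        if (is.null(outgroup_species))
          stop("stage scan[PHYLO]: no outgroup species supplied")
        og_row <- rownames(aln$mat)[aln$species == outgroup_species][1L]
        pf <- phylo_footprint(aln, og_row)
        build_catalog(ingroup, ingroup_tree, "PHYLO", static_track = pf$track,
                      singleton_filter = singleton_filter, exempt = exempt)
      },
      build_catalog(ingroup, ingroup_tree, m, library = library,
                    singleton_filter = singleton_filter, exempt = exempt))
    catalogs[[m]] <- cat_m
    write_catalog(cat_m, file.path(out_dir, paste0("catalog_", m, ".tsv")))

    tab <- catalog_mk_table(cat_m)
    mk_rows[[m]] <- data.frame(
      method = m, fixed_tfbs = tab$fixed_tfbs, fixed_ntfbs = tab$fixed_ntfbs,
      poly_tfbs = tab$poly_tfbs, poly_ntfbs = tab$poly_ntfbs,
      fisher_p = mk_fisher_test(tab))

    tot <- cat_m$totals
    n_gl <- sum(tot["fixed", c("gain", "loss")])
    n_ch <- tot["fixed", "change"]
    n_fixed <- sum(tot["fixed", ])
    frac <- cat_m$base_fraction$mean
    eq <- if (n_fixed > 0 && frac > 0 && frac < 1)
      equilibrium_relative_rate(n_gl, n_ch, n_fixed, frac) else
      list(equilibrium_tfbs_subs = NA, relative_rate = NA, percent_change = NA)
    in_subs <- sum(tot["fixed", c("gain", "loss", "change", "in_site")])
    fr <- if (n_fixed > in_subs && frac > 0 && frac < 1)
      footprint_relative_rate(in_subs, n_fixed - in_subs, frac, 1 - frac) else
      list(relative_rate = NA, percent_change = NA)
    rate_rows[[m]] <- data.frame(
      method = m, frac_tfbs = frac, fixed_total = n_fixed,
      equilibrium_tfbs_subs = eq$equilibrium_tfbs_subs,
      equilibrium_relative_rate = eq$relative_rate,
      equilibrium_percent_change = eq$percent_change,
      footprint_relative_rate = fr$relative_rate,
      footprint_percent_change = fr$percent_change)
  }
  mk <- do.call(rbind, mk_rows)
  rates <- do.call(rbind, rate_rows)
  utils::write.table(mk, file.path(out_dir, "table_mk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(rates, file.path(out_dir, "rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")

  manifest <- list(package = "crekit",
                   version = as.character(utils::packageVersion("crekit")),
                   methods = methods,
                   n_haplotypes = nrow(ingroup$mat),
                   n_species = length(alignment_species(ingroup)),
                   columns = ingroup$length,
                   singleton_filter = singleton_filter, exempt = exempt)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(diversity = div, profile = prof, catalogs = catalogs,
                 mk = mk, rates = rates))
}
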