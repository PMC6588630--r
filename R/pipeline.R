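# End-to-end orchestration of a synthetic repertoire study: genome
# simulation, mining, repertoire association statistics, family evolution
# and reconciliation, gene-conversion testing, selection analysis, and
# expression contrasts. Stages communicate only via on-disk files in the
# declared formats, so any stage's input can be replaced by externally
# produced files; a JSON manifest records inputs, parameters, seeds, and
# output checksums.

#' Default configuration for the bundled synthetic study
#'
#' Two "fright" and two "no-fright" species; fright species carry more
#' receptor genes with the surplus concentrated in one subfamily.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return Named list of configuration values.
#' @export
demo_config <- function(out_dir = tempfile("chemorep_run_"), seed = 1L) {
  list(
    out_dir = out_dir, seed = as.integer(seed),
    stages = c("genomes", "mine", "repertoire", "family", "geneconv",
               "selection", "expression"),
    species_fright = c("zeb", "cat"),
    species_nofright = c("cav", "eel"),
    n_intact_fright = 6L, n_intact_nofright = 3L,
    n_truncated = 1L, n_pseudo = 2L,
    divergence = 0.1, contig_len = 30000L,
    e_cutoff = 1e-10, max_gap = 5000L, flank = 10000L, completeness = 0.9,
    boosted_subfamily = "sf9",
    anosim_perms = 999L,
    n_codons = 120L, selection_taxa = 5L,
    expr_genes = 400L, expr_reps = 3L
  )
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` comments allowed; commas split
#' multi-valued entries; numeric-looking values are converted.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}

stage_deps <- c(mine = "genomes", repertoire = "mine")

#' Run the synthetic repertoire study pipeline
#'
#' Executes the enabled stages in order, writing every stage's outputs under
#' `config$out_dir` and a `manifest.json` with parameters, seeds and output
#' checksums. Identical configurations produce identical manifests.
#'
#' @param config Named list (see [demo_config()]) or path to a key-value
#'   configuration file.
#' @return Invisibly, the run report: per-species I/T/P counts, repertoire
#'   association statistics, per-branch gain/loss table, gene-conversion and
#'   selection results, expression contrasts.
#' @export
run_pipeline <- function(config = demo_config()) {
  if (is.character(config)) config <- utils::modifyList(demo_config(),
                                                        read_config(config))
  cfg <- config
  if (is.null(cfg$seed)) stop("config must set a seed")
  stages <- cfg$stages
  for (s in names(stage_deps)) {
    if (s %in% stages && !(stage_deps[[s]] %in% stages)) {
      stop("dependency error: stage '", s, "' requires stage '",
           stage_deps[[s]], "'")
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  message("chemorep run: out_dir=", cfg$out_dir, " seed=", cfg$seed)
  report <- list(config = cfg)
  species <- c(cfg$species_fright, cfg$species_nofright)
  ecotype <- stats::setNames(rep(c("fright", "no_fright"),
                                 c(length(cfg$species_fright),
                                   length(cfg$species_nofright))), species)
  queries <- c(synthetic_seed_protein(280L, seed = 101L),
               synthetic_seed_protein(280L, seed = 109L))
  names(queries) <- c("sf1", "sf9")

  if ("genomes" %in% stages) {
    for (i in seq_along(species)) {
      sp <- species[i]
      boost <- if (ecotype[sp] == "fright") cfg$n_intact_fright else
        cfg$n_intact_nofright
      sim <- simulate_receptor_genome(
        queries, n_intact = boost, n_truncated = cfg$n_truncated,
        n_pseudo = cfg$n_pseudo, divergence = cfg$divergence,
        contig_len = cfg$contig_len, seed = cfg$seed * 1000L + i)
      write_fasta(sim$contigs, file.path(cfg$out_dir,
                                         paste0(sp, "_genome.fasta")))
      utils::write.table(sim$truth,
                         file.path(cfg$out_dir, paste0(sp, "_truth.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("mine" %in% stages) {
    itp <- NULL
    counts <- matrix(0L, length(species), length(queries),
                     dimnames = list(species, names(queries)))
    for (sp in species) {
      genome_path <- file.path(cfg$out_dir, paste0(sp, "_genome.fasta"))
      if (!file.exists(genome_path)) {
        stop("dependency error: missing genome for species ", sp)
      }
      contigs <- read_fasta(genome_path)
      mined <- mine_receptors(contigs, queries, e_cutoff = cfg$e_cutoff,
                              max_gap = cfg$max_gap, flank = cfg$flank,
                              completeness = cfg$completeness)
      ann <- mined$annotations
      annotations_to_gff(ann, file.path(cfg$out_dir, paste0(sp, "_genes.gff")),
                         params = list(species = sp, seed = cfg$seed))
      prot <- vapply(mined$models, `[[`, character(1), "protein")
      keep <- ann$status != "pseudogene"
      if (any(keep)) {
        write_fasta(stats::setNames(prot[keep],
                                    sprintf("%s_g%d", sp, which(keep))),
                    file.path(cfg$out_dir, paste0(sp, "_proteins.fasta")))
      }
      itp <- rbind(itp, data.frame(
        species = sp, ecotype = ecotype[sp],
        intact = sum(ann$status == "intact"),
        truncated = sum(ann$status == "truncated"),
        pseudogene = sum(ann$status == "pseudogene"),
        stringsAsFactors = FALSE))
      intact <- ann[ann$status == "intact", , drop = FALSE]
      tab <- table(factor(intact$best_query, levels = names(queries)))
      counts[sp, ] <- as.integer(tab)
    }
    utils::write.table(itp, file.path(cfg$out_dir, "itp_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_table(counts, file.path(cfg$out_dir, "repertoire_matrix.tsv"),
                       extra = list(ecotype = unname(ecotype[species])))
    report$itp <- itp
  }

  if ("repertoire" %in% stages) {
    mat_path <- file.path(cfg$out_dir, "repertoire_matrix.tsv")
    if (!file.exists(mat_path)) stop("dependency error: no repertoire matrix")
    m <- read_matrix_table(mat_path)
    eco <- attr(m, "ecotype")
    an <- anosim_test(m, eco, n_perm = cfg$anosim_perms, seed = cfg$seed)
    pc <- tryCatch(pca_repertoire(m), error = function(e) NULL)
    top <- rownames(m)[which.max(rowSums(m))]
    bottom <- rownames(m)[which.min(rowSums(m))]
    report$repertoire <- list(anosim_R = an$R, anosim_p = an$p,
                              pca_var = if (is.null(pc)) NULL
                                        else pc$var_explained,
                              top_species = top, bottom_species = bottom)
    utils::write.table(
      data.frame(stat = c("anosim_R", "anosim_p"),
                 value = c(an$R, an$p)),
      file.path(cfg$out_dir, "repertoire_stats.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("family" %in% stages) {
    st <- ape::read.tree(text = sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                                        species[1], species[2], species[3],
                                        species[4]))
    fam <- simulate_family_evolution(st, birth = 0.3, death = 0.1,
                                     n_root = 2L, seed = cfg$seed + 7L)
    if (!fam$extinct && length(fam$gene_tree$tip.label) >= 2L) {
      write_newick(fam$gene_tree, file.path(cfg$out_dir, "gene_tree.nwk"))
      write_newick(st, file.path(cfg$out_dir, "species_tree.nwk"))
      rec <- reconcile_dl(fam$gene_tree, st)
      ev <- event_table(rec)
      utils::write.table(ev, file.path(cfg$out_dir, "reconciliation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$reconciliation <- ev
    } else {
      report$reconciliation <- "family extinct"
    }
  }

  if ("geneconv" %in% stages) {
    tr <- ape::read.tree(text = "(a:0.08,b:0.08,c:0.08,d:0.08);")
    sim <- simulate_codon_alignment(
      tr, list(list(prop = 1, omega = 0.5)), kappa = 2,
      n_codons = cfg$n_codons, seed = cfg$seed + 11L)
    gc_res <- conversion_test(sim$alignment, n_perm = 1000L,
                              seed = cfg$seed + 13L)
    utils::write.table(gc_res$pairs,
                       file.path(cfg$out_dir, "geneconv_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$geneconv <- list(global_p = gc_res$global_p,
                            n_polymorphic = gc_res$n_polymorphic)
  }

  if ("selection" %in% stages) {
    tr <- caterpillar_tree(cfg$selection_taxa, 0.3)
    sim <- simulate_codon_alignment(
      tr, list(list(prop = 0.8, omega = 0.2), list(prop = 0.2, omega = 2.5)),
      kappa = 2, n_codons = cfg$n_codons, seed = cfg$seed + 17L)
    m1a <- fit_site_model(sim$alignment, tr, "M1a", starts = 1L,
                          seed = cfg$seed)
    m2a <- fit_site_model(sim$alignment, tr, "M2a", starts = 1L,
                          seed = cfg$seed, lengths = m1a$lengths)
    lrt <- likelihood_ratio_test(m2a, m1a, df = 2)
    sel <- data.frame(model = c("M1a", "M2a"),
                      lnL = c(m1a$lnL, m2a$lnL),
                      np = c(m1a$np, m2a$np),
                      stat = c(NA, lrt$stat), p = c(NA, lrt$p))
    utils::write.table(sel, file.path(cfg$out_dir, "selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$selection <- sel
  }

  if ("expression" %in% stages) {
    ex <- simulate_expression_counts(n_genes = cfg$expr_genes,
                                     n_per_group = cfg$expr_reps,
                                     dispersion = 0.1, de_fraction = 0.15,
                                     log2fc = 2, seed = cfg$seed + 23L)
    sets <- list(planted_de = ex$is_de)
    summ <- expression_change_summary(ex$counts, ex$lengths, ex$condition,
                                      sets, focal = "planted_de")
    utils::write.table(summ$tests,
                       file.path(cfg$out_dir, "expression_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$expression <- summ$tests
  }

  manifest <- list(
    seed = cfg$seed,
    stages = stages,
    parameters = cfg[setdiff(names(cfg), c("out_dir", "stages"))],
    outputs = local({
      fs <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
      stats::setNames(as.list(unname(tools::md5sum(
        file.path(cfg$out_dir, fs)))), fs)
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
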