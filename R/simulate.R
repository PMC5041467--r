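## Synthetic test worlds: a small taxonomy, a structured RNA family evolved
## along it with compensatory base-pair mutations, family instances embedded
## in random decoy contigs, and a truth table of planted locations.  Every
## generator output is deterministic given the spec seed.

WC_PARTNER <- c(A = "U", C = "G", G = "C", U = "A")

## Fixed 70-nt seed: hairpin with an internal helix and a 3-nt bulge on each
## side, 6-nt tails.  Stems cycle strong pairs, loops are A/C-rich.
default_seed_structure <- function() {
  paste0("......", strrep("(", 14), "...", strrep("(", 9), "......",
         strrep(")", 9), "...", strrep(")", 14), "......")
}

default_seed_sequence <- function(structure = default_seed_structure()) {
  n <- nchar(structure)
  ch <- rep(NA_character_, n)
  pairs <- dotbracket_pairs(structure)
  pair_cycle <- list(c("G", "C"), c("C", "G"), c("A", "U"),
                     c("G", "C"), c("U", "A"), c("C", "G"))
  for (k in seq_len(nrow(pairs))) {
    p <- pair_cycle[[(k - 1L) %% length(pair_cycle) + 1L]]
    ch[pairs[k, 1]] <- p[1]
    ch[pairs[k, 2]] <- p[2]
  }
  loop_cycle <- c("A", "C", "A", "A", "C", "U")
  un <- which(is.na(ch))
  ch[un] <- loop_cycle[(seq_along(un) - 1L) %% length(loop_cycle) + 1L]
  paste(ch, collapse = "")
}

## Default desk-scale taxonomy: 12 family-bearing taxa over 4 levels, plus
## one decoy species under every internal node.
default_sim_taxonomy <- function(decoys_per_internal = 1L) {
  nodes <- tibble(
    taxid  = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    parent = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 6L, 7L),
    rank   = c("root", "domain", "domain", "genus", "genus", "genus",
               "genus", "species", "species", "species", "species", "species"),
    name   = c("root", "domA", "domB", "genA1", "genA2", "genB1", "genB2",
               "spA1a", "spA1b", "spA2a", "spB1a", "spB2a")
  )
  internal <- unique(nodes$parent)
  decoys <- tibble()
  if (decoys_per_internal > 0L) {
    rows <- list()
    for (p in internal) {
      for (d in seq_len(decoys_per_internal)) {
        rows[[length(rows) + 1L]] <- tibble(
          taxid = 100L * d + p, parent = p, rank = "species",
          name = paste0("decoy_", p, "_", d))
      }
    }
    decoys <- bind_rows(rows)
  }
  list(tree = taxonomy_tree(bind_rows(nodes, decoys)),
       family_taxa = nodes$taxid, decoy_taxa = decoys$taxid %||% integer(0))
}

#' Specification of a synthetic family world
#'
#' Defaults define the desk-scale study world: a 12-taxon, depth-4 taxonomy
#' (plus one decoy species per internal node), a 70-nt hairpin-with-bulge
#' seed, 0.05 expected substitutions per site per branch with 80%
#' compensatory rescue at paired sites, rare single-nucleotide loop indels,
#' and 3-kb contigs with uniform background.
#'
#' @param seed_seq,seed_structure seed sequence and dot-bracket structure
#'   (consistent lengths); defaults are the built-in 70-nt hairpin.
#' @param rate expected substitutions per site per branch.
#' @param compensatory probability that a substitution at a paired site is
#'   rescued by the Watson-Crick complement at the partner site.
#' @param loop_indel_rate per-site probability of a single-nucleotide
#'   insertion/deletion at unpaired sites, per branch.
#' @param contig_length length of each generated contig (> 2x family length).
#' @param decoys_per_internal decoy species added under each internal node.
#' @param gc background GC content.
#' @param seed integer RNG seed for all generator randomness.
#' @param branch_rates optional named numeric vector overriding `rate` on
#'   individual branches; names are the child taxon ids.  Used e.g. to make
#'   one clade strongly divergent.
#' @return a `family_sim_spec` object.
#' @export
family_sim_spec <- function(seed_seq = NULL, seed_structure = NULL,
                            rate = 0.03, compensatory = 0.8,
                            loop_indel_rate = 0.01, contig_length = 3000L,
                            decoys_per_internal = 1L, gc = 0.5, seed = 42L,
                            branch_rates = NULL) {
  seed_structure <- seed_structure %||% default_seed_structure()
  seed_seq <- seed_seq %||% default_seed_sequence(seed_structure)
  if (nchar(seed_seq) != nchar(seed_structure)) {
    stop("spec error: seed sequence and structure lengths differ")
  }
  if (!is_balanced_dotbracket(seed_structure)) {
    stop("spec error: seed structure is not balanced")
  }
  stopifnot(rate >= 0, rate <= 1, compensatory >= 0, compensatory <= 1,
            loop_indel_rate >= 0, loop_indel_rate <= 1)
  if (contig_length <= 2L * nchar(seed_seq)) {
    stop("spec error: contig_length must exceed twice the family length")
  }
  tax <- default_sim_taxonomy(decoys_per_internal)
  structure(list(
    seed_seq = seed_seq, seed_structure = seed_structure,
    taxonomy = tax$tree, family_taxa = tax$family_taxa,
    decoy_taxa = tax$decoy_taxa,
    rate = rate, branch_rates = branch_rates, compensatory = compensatory,
    loop_indel_rate = loop_indel_rate,
    contig_length = as.integer(contig_length), gc = gc,
    seed = as.integer(seed)
  ), class = "family_sim_spec")
}

mutate_branch <- function(chars, db, rate, compensatory, indel_rate) {
  n <- length(chars)
  pairs <- dotbracket_pairs(paste(db, collapse = ""))
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  n_sub <- rpois(1, rate * n)
  if (n_sub > 0L) {
    pos <- sample.int(n, min(n_sub, n))
    for (p in pos) {
      new <- sample(setdiff(RNA_ALPHABET, chars[p]), 1)
      chars[p] <- new
      if (!is.na(partner[p]) && runif(1) < compensatory) {
        chars[partner[p]] <- WC_PARTNER[[new]]
      }
    }
  }
  if (indel_rate > 0) {
    loop_pos <- which(db == ".")
    hit <- loop_pos[runif(length(loop_pos)) < indel_rate]
    for (p in sort(hit, decreasing = TRUE)) {   # back-to-front keeps indices valid
      if (runif(1) < 0.5 && length(chars) > 1L) {
        chars <- chars[-p]
        db <- db[-p]
      } else {
        chars <- append(chars, sample(RNA_ALPHABET, 1), after = p)
        db <- append(db, ".", after = p)
      }
    }
  }
  list(chars = chars, db = db)
}

#' Evolve a family along the taxonomy
#'
#' The root carries the seed; each child's sequence is its parent's with
#' `Poisson(rate * length)` substitutions.  A substitution at a paired site
#' is compensatory with probability `compensatory` (the partner mutates to
#' the Watson-Crick complement, preserving the pair), otherwise it breaks
#' the pair.  Unpaired sites gain or lose single nucleotides at
#' `loop_indel_rate`.  Deterministic given the spec seed.
#'
#' @param spec a [family_sim_spec()].
#' @return named list (by taxon id) of `list(seq, structure)` for every
#'   family-bearing taxon.
#' @export
evolve_family <- function(spec) {
  stopifnot(inherits(spec, "family_sim_spec"))
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  tree <- spec$taxonomy
  fam <- list()
  root <- tree$root
  fam[[as.character(root)]] <- list(chars = str_chars(spec$seed_seq),
                                    db = str_chars(spec$seed_structure))
  ## breadth-first by taxid order for determinism
  todo <- sort(setdiff(spec$family_taxa, root))
  done <- root
  while (length(todo)) {
    ready <- todo[vapply(todo, function(t) parent_of(tree, t) %in% done, logical(1))]
    for (t in ready) {
      par <- fam[[as.character(parent_of(tree, t))]]
      br <- spec$rate
      if (as.character(t) %in% names(spec$branch_rates)) {
        br <- unname(spec$branch_rates[[as.character(t)]])
      }
      ## per-branch RNG substream: changing one branch's rate leaves every
      ## other branch's mutations untouched
      set.seed(derive_seed(spec$seed, 1000L + t))
      fam[[as.character(t)]] <- mutate_branch(par$chars, par$db, br,
                                              spec$compensatory,
                                              spec$loop_indel_rate)
    }
    done <- c(done, ready)
    todo <- setdiff(todo, ready)
  }
  lapply(fam, function(x) list(seq = paste(x$chars, collapse = ""),
                               structure = paste(x$db, collapse = "")))
}

random_background <- function(n, gc) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Embed family instances in decoy contigs
#'
#' Each family taxon gets a uniform-random background contig with its family
#' instance inserted at a random position on a random strand; decoy taxa get
#' pure background.  The truth table records the exact planted coordinates
#' (0-based half-open, plus strand) and each instance's identity to the seed.
#'
#' @param family output of [evolve_family()].
#' @param spec the [family_sim_spec()].
#' @return list with `contigs` (tibble `id`, `seq`, `taxid`) and `truth`
#'   (tibble `contig`, `taxid`, `start`, `end`, `strand`,
#'   `identity_to_seed`).
#' @export
embed_in_genomes <- function(family, spec) {
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 2L))
  contigs <- list()
  truth <- list()
  for (tx in sort(as.integer(names(family)))) {
    inst <- family[[as.character(tx)]]$seq
    L <- nchar(inst)
    bg <- random_background(spec$contig_length, spec$gc)
    pos <- sample.int(spec$contig_length - L + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") inst else reverse_complement(inst)
    seq <- paste0(substr(bg, 1, pos), ins,
                  substr(bg, pos + 1L, spec$contig_length - L))
    id <- paste0("contig_t", tx)
    contigs[[length(contigs) + 1L]] <- tibble(id = id, seq = seq, taxid = tx)
    truth[[length(truth) + 1L]] <- tibble(
      contig = id, taxid = tx, start = pos, end = pos + L, strand = strand,
      identity_to_seed = sequence_identity(inst, spec$seed_seq))
  }
  for (tx in spec$decoy_taxa) {
    contigs[[length(contigs) + 1L]] <- tibble(
      id = paste0("contig_t", tx),
      seq = random_background(spec$contig_length, spec$gc), taxid = tx)
  }
  list(contigs = bind_rows(contigs), truth = bind_rows(truth))
}

#' Generate a complete synthetic world
#'
#' @param spec a [family_sim_spec()].
#' @return a `sim_world`: list with `spec`, `taxonomy`, `family`, `contigs`,
#'   `truth`.
#' @export
simulate_world <- function(spec = family_sim_spec()) {
  family <- evolve_family(spec)
  emb <- embed_in_genomes(family, spec)
  structure(list(spec = spec, taxonomy = spec$taxonomy, family = family,
                 contigs = emb$contigs, truth = emb$truth),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world> ", length(x$family), " planted instances, ",
      nrow(x$contigs), " contigs of ", x$spec$contig_length, " nt\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits the taxonomy TSV, the target multi-FASTA with `taxid=` headers, the
#' truth TSV and a JSON record of the generating parameters.
#'
#' @param world a `sim_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxonomy(world$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_fasta(world$contigs, file.path(dir, "targets.fa"))
  utils::write.table(as.data.frame(world$truth), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- world$spec
  jsonlite::write_json(
    list(seed_seq = sp$seed_seq, seed_structure = sp$seed_structure,
         rate = sp$rate, compensatory = sp$compensatory,
         loop_indel_rate = sp$loop_indel_rate,
         contig_length = sp$contig_length, gc = sp$gc, seed = sp$seed),
    file.path(dir, "spec.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Run the full pipeline against a synthetic world
#'
#' Uses one planted leaf instance as the pipeline input (with its taxon as
#' the starting point) and scores the reconstruction against the truth
#' table.
#'
#' @param spec a [family_sim_spec()].
#' @param cfg a [pipeline_config()].
#' @param input_taxon taxon whose planted instance seeds the run (default:
#'   the lowest-numbered leaf, taxid 8 in the default world).
#' @param backends backend list from [default_backends()].
#' @return list with `world`, `result` (a `family_result`) and `report` (a
#'   `recovery_report`).
#' @export
benchmark_run <- function(spec = family_sim_spec(), cfg = pipeline_config(),
                          input_taxon = NULL, backends = default_backends()) {
  world <- simulate_world(spec)
  leaves <- setdiff(spec$family_taxa,
                    unique(world$taxonomy$nodes$parent))
  input_taxon <- input_taxon %||% min(leaves)
  tr <- world$truth[world$truth$taxid == input_taxon, , drop = FALSE]
  if (nrow(tr) != 1L) stop("no planted instance for taxon ", input_taxon)
  contig <- world$contigs[world$contigs$id == tr$contig, , drop = FALSE]
  input <- extract_region(contig[1, ], tr$start, tr$end, tr$strand)
  input$id <- "input"
  result <- run_family_pipeline(input, taxid = input_taxon,
                                taxonomy = world$taxonomy,
                                targets = world$contigs,
                                cfg = cfg, backends = backends)
  report <- recovery_report(result$members, world$truth)
  list(world = world, result = result, report = report)
}
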