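# Deterministic synthetic study generator. Emulates the melanoma
# Decitabine study design: a small GO-like DAG with apoptosis-like and
# proliferation-like subtrees, RefSeq-shaped gene accessions annotated into
# those subtrees, a partially recursive transcription-factor network, and
# two per-sample observation datasets ("Methylation Relative" and "AZA
# Pre-Post Treatment Ratios") with a planted sensitive/resistant signal.
# Every ground-truth oracle here is computed with plain set/matrix code,
# independent of the entailment and query machinery it validates.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the seven-cell-line design of the original study: 7
#' samples, 5 sensitive and 2 resistant, with apoptosis-subtree genes
#' passing both analysis filters at rate 0.3 in sensitive samples and 0.05
#' in resistant ones, against a 0.05 background rate.
#'
#' @param seed Integer RNG seed; identical configurations produce
#'   byte-identical files and ground truth.
#' @param n_terms DAG size (>= 3: root plus the two subtree roots).
#' @param n_genes Gene universe size.
#' @param n_tfs Number of transcription factors.
#' @param n_samples Number of samples.
#' @param sensitive_samples Character vector of sensitive sample titles;
#'   default the first 5 generated titles.
#' @param apoptosis_hit_rate_sensitive,apoptosis_hit_rate_resistant
#'   Probability that an apoptosis-subtree gene passes both filters in a
#'   sensitive / resistant sample.
#' @param background_hit_rate Same probability for all other genes.
#' @param cycle_prob Probability that a factor's regulated set includes
#'   another factor's expressing gene, creating recursion and cycles.
#' @param apoptosis_gene_frac,proliferation_gene_frac Fractions of the
#'   gene universe annotated into each subtree (the remainder is
#'   background, annotated to the root).
#' @param multi_map_frac Fraction of gene symbols that map to a second
#'   RefSeq accession.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_terms = 60, n_genes = 1000,
                             n_tfs = 10, n_samples = 7,
                             sensitive_samples = NULL,
                             apoptosis_hit_rate_sensitive = 0.3,
                             apoptosis_hit_rate_resistant = 0.05,
                             background_hit_rate = 0.05,
                             cycle_prob = 0.15,
                             apoptosis_gene_frac = 0.3,
                             proliferation_gene_frac = 0.1,
                             multi_map_frac = 0.05) {
  stopifnot(n_terms >= 3, n_genes >= 1, n_samples >= 1)
  titles <- sprintf("MEL%02d", seq_len(n_samples))
  if (is.null(sensitive_samples)) {
    sensitive_samples <- titles[seq_len(min(5, n_samples))]
  }
  if (!all(sensitive_samples %in% titles)) {
    abort("sensitive_samples must be a subset of the generated sample titles")
  }
  rates <- c(apoptosis_hit_rate_sensitive, apoptosis_hit_rate_resistant,
             background_hit_rate, cycle_prob)
  stopifnot(all(rates >= 0 & rates <= 1))
  structure(list(
    seed = as.integer(seed), n_terms = n_terms, n_genes = n_genes,
    n_tfs = n_tfs, n_samples = n_samples, sample_titles = titles,
    sensitive_samples = sensitive_samples,
    apoptosis_hit_rate_sensitive = apoptosis_hit_rate_sensitive,
    apoptosis_hit_rate_resistant = apoptosis_hit_rate_resistant,
    background_hit_rate = background_hit_rate,
    cycle_prob = cycle_prob,
    apoptosis_gene_frac = apoptosis_gene_frac,
    proliferation_gene_frac = proliferation_gene_frac,
    multi_map_frac = multi_map_frac
  ), class = "synthetic_config")
}

# run code under a local, restored RNG state
with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# independent transitive-closure oracle over a child -> parent edge list,
# by boolean matrix powers
reach_closure <- function(nodes, edges, min_len = 1L) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) adj[cbind(edges[[1]], edges[[2]])] <- TRUE
  acc <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  p <- diag(n) == 1
  for (len in seq_len(n)) {
    p <- (p %*% adj) > 0
    if (len >= min_len) acc <- acc | p
    if (!any(p)) break
  }
  acc
}

#' Generate a rooted concept DAG with apoptosis- and proliferation-like subtrees
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `obo_lines` (an OBO 1.2 document), `terms`
#'   (tibble `id`, `name`, `subtree` in root/apoptosis/proliferation),
#'   `edges` (`child`, `parent`), `apoptosis_term`, `proliferation_term`,
#'   `root_term`, and `ancestors` — a named list of proper-ancestor sets
#'   computed by an independent matrix-power oracle.
#' @export
simulate_concept_dag <- function(cfg) {
  # the three anchor terms carry their real GO accessions so that queries
  # written against the genuine ontology run unchanged on synthetic data
  ids <- c("GO:0008150", "GO:0006915", "GO:0008283",
           if (cfg$n_terms > 3) sprintf("GO:%07d", seq_len(cfg$n_terms - 3)))
  root <- ids[1]; apop <- ids[2]; prolif <- ids[3]
  subtree <- c("root", "apoptosis", "proliferation")
  edges <- tibble(child = c(apop, prolif), parent = c(root, root))
  with_local_seed(cfg$seed + 11L, {
    if (cfg$n_terms > 3) {
      for (i in 4:cfg$n_terms) {
        side <- if (runif(1) < 0.5) "apoptosis" else "proliferation"
        pool <- ids[seq_len(i - 1)][subtree == side]
        parent <- sample(pool, 1)
        subtree <- c(subtree, side)
        edges <- bind_rows(edges, tibble(child = ids[i], parent = parent))
        if (length(pool) > 1 && runif(1) < 0.25) {
          second <- sample(setdiff(pool, parent), 1)
          edges <- bind_rows(edges, tibble(child = ids[i], parent = second))
        }
      }
    }
  })
  names <- c("biological_process", "apoptosis", "cell proliferation",
             if (cfg$n_terms > 3) sprintf("synthetic process %02d", 4:cfg$n_terms))
  terms <- tibble(id = ids, name = names, subtree = subtree)
  reach <- reach_closure(ids, edges, min_len = 1L)
  ancestors <- lapply(setNames(ids, ids), function(t) sort(ids[reach[t, ]]))
  obo_lines <- c(
    "format-version: 1.2",
    "ontology: synthetic-go",
    unlist(lapply(seq_len(cfg$n_terms), function(i) {
      kid <- ids[i]
      parents <- edges$parent[edges$child == kid]
      c("", "[Term]", paste0("id: ", kid), paste0("name: ", names[i]),
        "namespace: biological_process",
        if (length(parents) > 0) paste0("is_a: ", parents))
    }))
  )
  list(obo_lines = obo_lines, terms = terms, edges = edges,
       root_term = root, apoptosis_term = apop, proliferation_term = prolif,
       ancestors = ancestors)
}

#' Generate gene annotations and a symbol map for a synthetic DAG
#'
#' Genes are RefSeq-shaped accessions (`NM_` + 6 digits). Apoptosis-class
#' genes annotate into the apoptosis subtree, proliferation-class genes
#' into the proliferation subtree, background genes to the root; each gene
#' carries 1-3 aspect-P annotations. Symbols map one-to-one to accessions
#' except for a configured fraction that also map to a second accession.
#'
#' @param cfg A [synthetic_config()].
#' @param dag Output of [simulate_concept_dag()].
#' @return A list with `gaf_lines`, `symbol_map_lines`, `genes` (tibble
#'   `accession`, `symbol`, `class`), `annotations` (tibble `symbol`,
#'   `accession`, `go_id`) and `annotated_closure` — the per-accession
#'   annotation sets closed over the DAG's independent ancestor oracle.
#' @export
simulate_annotations <- function(cfg, dag) {
  n <- cfg$n_genes
  accession <- sprintf("NM_%06d", seq_len(n))
  symbol <- sprintf("SYN%05d", seq_len(n))
  n_apop <- round(cfg$apoptosis_gene_frac * n)
  n_prolif <- round(cfg$proliferation_gene_frac * n)
  class <- c(rep("apoptosis", n_apop), rep("proliferation", n_prolif),
             rep("background", n - n_apop - n_prolif))
  pools <- list(
    apoptosis = dag$terms$id[dag$terms$subtree == "apoptosis"],
    proliferation = dag$terms$id[dag$terms$subtree == "proliferation"],
    background = dag$root_term
  )
  with_local_seed(cfg$seed + 23L, {
    ann <- lapply(seq_len(n), function(i) {
      pool <- pools[[if (class[i] == "background") "background" else class[i]]]
      k <- sample(1:3, 1)
      unique(sample(pool, min(k, length(pool))))
    })
    extra_idx <- which(runif(n) < cfg$multi_map_frac)
  })
  extra_acc <- sprintf("NM_9%05d", seq_along(extra_idx))
  map_tbl <- bind_rows(
    tibble(symbol = symbol, refseq = accession),
    tibble(symbol = symbol[extra_idx], refseq = extra_acc)
  )
  ann_tbl <- bind_rows(lapply(seq_len(n), function(i) {
    tibble(symbol = symbol[i], go_id = ann[[i]])
  }))
  ann_expanded <- inner_join(ann_tbl, map_tbl, by = "symbol",
                             relationship = "many-to-many") %>%
    select(symbol = "symbol", accession = "refseq", go_id = "go_id")
  closure <- lapply(split(ann_expanded$go_id, ann_expanded$accession),
                    function(terms) {
    sort(unique(c(terms, unlist(dag$ancestors[terms], use.names = FALSE))))
  })
  gaf_lines <- c(
    "!gaf-version: 2.1",
    sprintf("SYNT\t%s\t%s\t\t%s\tSYNT:0001\tIEA\t\tP\t\t\ttranscript\ttaxon:9606\t20120101\tSYNT\t\t",
            ann_tbl$symbol, ann_tbl$symbol, ann_tbl$go_id)
  )
  list(
    gaf_lines = gaf_lines,
    symbol_map_lines = paste0(map_tbl$symbol, "\t", map_tbl$refseq),
    genes = tibble(accession = accession, symbol = symbol, class = class),
    annotations = ann_expanded,
    annotated_closure = closure
  )
}

#' Generate a transcription-factor network with optional recursion
#'
#' Each factor is expressed by one gene and regulates a handful of genes;
#' with probability `cycle_prob` (per factor) the regulated set includes
#' another factor's expressing gene, which makes the coregulation network
#' recursive and possibly cyclic.
#'
#' @param cfg A [synthetic_config()].
#' @param ann Output of [simulate_annotations()].
#' @return A list with `tf_lines` (TSV), `records` (tibble `tf_id`,
#'   `expressing_gene`, list-column `regulated`), and ground-truth
#'   coregulation sets computed with an independent matrix oracle:
#'   `coregulates` (edge tibble), `two_step` and `closure` (named list of
#'   target sets per gene, paths of length exactly 2 and >= 2).
#' @export
simulate_tf_network <- function(cfg, ann) {
  genes <- ann$genes$accession
  with_local_seed(cfg$seed + 37L, {
    expressing <- sample(genes, cfg$n_tfs)
    records <- lapply(seq_len(cfg$n_tfs), function(i) {
      k <- sample(3:12, 1)
      targets <- sample(genes, k)
      if (cfg$n_tfs > 1 && runif(1) < cfg$cycle_prob) {
        targets <- c(targets, sample(expressing[-i], 1))
      }
      list(tf_id = sprintf("V$TF%02d_01", i),
           expressing_gene = expressing[i],
           regulated = sort(unique(targets)))
    })
  })
  rec_tbl <- tibble(
    tf_id = map_chr(records, "tf_id"),
    expressing_gene = map_chr(records, "expressing_gene"),
    regulated = map(records, "regulated")
  )
  long <- bind_rows(lapply(records, function(r) {
    tibble(tf_id = r$tf_id,
           role = c("expresses", rep("regulates", length(r$regulated))),
           refseq = c(r$expressing_gene, r$regulated))
  }))
  coreg <- distinct(tidyr::unnest(rec_tbl, "regulated") %>%
                      select(gene = "expressing_gene", target = "regulated"))
  nodes <- sort(unique(c(coreg$gene, coreg$target)))
  closure2 <- reach_closure(nodes, coreg, min_len = 2L)
  exact2 <- {
    n <- length(nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    adj[cbind(coreg$gene, coreg$target)] <- TRUE
    (adj %*% adj) > 0
  }
  list(
    tf_lines = c("tf_id\trole\trefseq",
                 paste0(long$tf_id, "\t", long$role, "\t", long$refseq)),
    records = rec_tbl,
    coregulates = coreg,
    two_step = lapply(setNames(nodes, nodes), function(g) sort(nodes[exact2[g, ]])),
    closure = lapply(setNames(nodes, nodes), function(g) sort(nodes[closure2[g, ]]))
  )
}

#' Generate the two observation datasets with a planted sensitivity signal
#'
#' For every sample and gene, the gene "hits" (methylation above 2 and
#' expression ratio above 1) with a probability set by the gene's class
#' and the sample's planted label: apoptosis-class genes hit at the
#' sensitive or resistant rate, all other genes at the background rate.
#' Hitting genes draw methylation from (2.5, 8) and ratio from (1.5, 5);
#' non-hitting genes from (0.2, 1.8) and (0.25, 0.95), so threshold
#' crossings — the only thing the analyses consume — are exact by
#' construction.
#'
#' @param cfg A [synthetic_config()].
#' @param ann Output of [simulate_annotations()].
#' @return A list with `methylation_lines` and `ratio_lines` (observation
#'   TSVs), `labels` (named character vector sample -> sensitive/
#'   resistant), and `hits` — the per-sample gene sets passing both
#'   filters, recorded at draw time.
#' @export
simulate_observations <- function(cfg, ann) {
  samples <- cfg$sample_titles
  genes <- ann$genes$accession
  is_apop <- ann$genes$class == "apoptosis"
  labels <- ifelse(samples %in% cfg$sensitive_samples, "sensitive", "resistant")
  names(labels) <- samples
  meth_rows <- list(); ratio_rows <- list(); hits <- list()
  with_local_seed(cfg$seed + 53L, {
    for (s in samples) {
      rate <- ifelse(is_apop,
                     if (labels[[s]] == "sensitive")
                       cfg$apoptosis_hit_rate_sensitive
                     else cfg$apoptosis_hit_rate_resistant,
                     cfg$background_hit_rate)
      hit <- runif(length(genes)) < rate
      meth <- ifelse(hit, runif(length(genes), 2.5, 8),
                     runif(length(genes), 0.2, 1.8))
      ratio <- ifelse(hit, runif(length(genes), 1.5, 5),
                      runif(length(genes), 0.25, 0.95))
      meth_rows[[s]] <- tibble(sample = s, gene = genes, value = meth)
      ratio_rows[[s]] <- tibble(sample = s, gene = genes, value = ratio)
      hits[[s]] <- genes[hit]
    }
  })
  meth <- bind_rows(meth_rows); ratio <- bind_rows(ratio_rows)
  obs_lines <- function(df, dataset, measure) {
    c("dataset\tsample\treporter_id\tvalue\tmeasure",
      sprintf("%s\t%s\t%s\t%s\t%s", dataset, df$sample, df$gene,
              format_double(df$value), measure))
  }
  list(
    methylation_lines = obs_lines(meth, "Methylation Relative",
                                  "methylation relative"),
    ratio_lines = obs_lines(ratio, "AZA Pre-Post Treatment Ratios",
                            "expression ratio"),
    labels = labels,
    hits = hits
  )
}

#' Generate a complete synthetic study with ground truth
#'
#' Runs the four generators and collects their emitted files and
#' ground-truth oracles. Identical configurations give byte-identical
#' output.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `config`, `dag`, `annotations`, `tf`,
#'   `observations`, and `files` — a named list of character vectors
#'   (`go.obo`, `annotations.gaf`, `sym2refseq.tsv`, `tf.tsv`,
#'   `methylation.tsv`, `ratios.tsv`).
#' @export
simulate_study <- function(cfg = synthetic_config()) {
  dag <- simulate_concept_dag(cfg)
  ann <- simulate_annotations(cfg, dag)
  tf <- simulate_tf_network(cfg, ann)
  obs <- simulate_observations(cfg, ann)
  list(
    config = cfg, dag = dag, annotations = ann, tf = tf, observations = obs,
    files = list(
      go.obo = dag$obo_lines,
      annotations.gaf = ann$gaf_lines,
      sym2refseq.tsv = ann$symbol_map_lines,
      tf.tsv = tf$tf_lines,
      methylation.tsv = obs$methylation_lines,
      ratios.tsv = obs$ratio_lines
    )
  )
}

#' Write a synthetic study's files to a directory
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_fixtures <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(study$files), function(nm) {
    p <- file.path(dir, nm)
    writeLines(study$files[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Build the merged, entailed semantic model of a synthetic study
#'
#' Convenience pipeline: parses the study's emitted files through the
#' package readers, maps observations, SKOS concepts, annotations and the
#' TF network to RDF, merges everything on the shared RefSeq URIs, and
#' materialises both entailments.
#'
#' @param study Output of [simulate_study()].
#' @param allow_self,indirect_depth Passed to [entail_tf()].
#' @param vocab Vocabulary.
#' @return The merged, entailed `rdf_graph`.
#' @export
semantic_model_from_study <- function(study, allow_self = TRUE,
                                      indirect_depth = "inf",
                                      vocab = rdf_vocabulary()) {
  scheme <- read_obo(study$files$go.obo)
  gaf <- read_gaf(study$files$annotations.gaf)
  symmap <- read_symbol_map(I(paste(study$files$sym2refseq.tsv, collapse = "\n")))
  tf_records <- read_tf_table(I(paste(study$files$tf.tsv, collapse = "\n")))
  obs <- bind_rows(
    read_observation_table(I(paste(study$files$methylation.tsv, collapse = "\n"))),
    read_observation_table(I(paste(study$files$ratios.tsv, collapse = "\n")))
  )
  merged <- rdf_merge(
    observations_to_rdf(obs, vocab),
    obo_to_skos(scheme, vocab),
    suppressMessages(annotations_to_rdf(gaf, symmap, scheme, vocab)),
    tf_to_rdf(tf_records, vocab)
  )
  merged <- entail_go(merged, vocab)
  entail_tf(merged, vocab, allow_self = allow_self,
            indirect_depth = indirect_depth)
}
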