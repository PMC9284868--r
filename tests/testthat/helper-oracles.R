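# Independent brute-force oracles kept deliberately separate from the
# package's own algorithms: reachability by boolean matrix closure,
# TP/FP/FN by raw set algebra on key strings, consensus by vote counting.

# compact constructor: edges as named list child -> parent vector
make_ont <- function(edges, id = "T") {
  iris <- unique(c(names(edges), unlist(edges, use.names = FALSE)))
  parents <- stats::setNames(vector("list", length(iris)), iris)
  for (i in iris) parents[[i]] <- character(0)
  for (ch in names(edges)) parents[[ch]] <- edges[[ch]]
  ontology(id, iris, parents)
}

chain_ontology <- function() {
  make_ont(list(a = "root", b = "a", c = "b"))
}

diamond_ontology <- function() {
  make_ont(list(a = "root", b = "a", c = "a", d = c("b", "c")))
}

# random rooted DAG with n nodes: node i picks 1-2 parents among 1..(i-1)
random_dag_ontology <- function(n, id = "R") {
  iris <- sprintf("n%02d", seq_len(n))
  parents <- stats::setNames(vector("list", n), iris)
  parents[[1]] <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[i]] <- sample(iris[seq_len(i - 1)], k)
  }
  ontology(id, iris, parents)
}

# oracle: full reachability matrix over child -> parent edges
# (row reaches column), by iterated boolean closure
reachability_oracle <- function(ont) {
  n <- length(ont$iris)
  adj <- matrix(FALSE, n, n, dimnames = list(ont$iris, ont$iris))
  for (ch in ont$iris) adj[ch, ont$parents[[ch]]] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% adj) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

oracle_ancestors <- function(reach, iri) {
  names(which(reach[iri, ]))
}

oracle_descendants <- function(reach, iri) {
  names(which(reach[, iri]))
}

# random alignment over class universes of the given sizes
random_alignment <- function(n, n_src = 30, n_tgt = 30,
                             src_id = "A", tgt_id = "B") {
  pairs <- unique(data.frame(
    source_iri = sprintf("a%03d", sample.int(n_src, n, replace = TRUE)),
    target_iri = sprintf("b%03d", sample.int(n_tgt, n, replace = TRUE)),
    stringsAsFactors = FALSE))
  alignment(src_id, tgt_id,
            mappings(pairs$source_iri, pairs$target_iri,
                     confidence = round(runif(nrow(pairs)), 3)))
}

oracle_classify <- function(a_keys, r_keys) {
  list(tp = intersect(a_keys, r_keys),
       fp = setdiff(a_keys, r_keys),
       fn = setdiff(r_keys, a_keys))
}

oracle_consensus <- function(key_sets, min_votes) {
  counts <- table(unlist(lapply(key_sets, unique)))
  sort(names(counts)[counts >= min_votes])
}

mapping_keys <- function(al) {
  paste(al$mappings$source_iri, al$mappings$target_iri, sep = "\r")
}

# small scenario used across tests (fast to generate)
small_scenario <- function(seed = 42, ...) {
  args <- list(
    seed = seed, n_categories_a = 6, n_categories_b = 6,
    category_map_fraction = 0.5, classes_per_category = 15,
    max_depth = 3, n_extra_parent_edges = 4,
    shared_concept_fraction = 0.5, cui_coverage = 0.9,
    matcher_recall = 0.7, n_false_mappings = 20,
    cross_category_fraction = 0.5)
  args <- utils::modifyList(args, list(...))
  generate_scenario(do.call(synthetic_config, args))
}
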