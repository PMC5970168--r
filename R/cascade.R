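# Tripartite MAPKKK -> MKK -> MAPK interaction graph, cascade-module
# enumeration under expression-based exclusions, and shared-response
# annotation.

KKK_PREFIXES <- c("MEKK", "ANP", "YDA", "RAF", "CTR", "EDR", "ZIK")

# Display-name aliases -> canonical ids (the interaction list and the
# cascade figure label the same MKK differently).
GENE_ALIASES <- c(MKK2 = "MKK2_2")

#' Normalize gene display names to canonical identifiers
#'
#' @param name Character vector of gene names.
#' @return Canonical names (e.g. `MKK2` becomes `MKK2_2`).
#' @export
normalize_gene_name <- function(name) {
  name <- as.character(name)
  hit <- match(name, names(GENE_ALIASES))
  name[!is.na(hit)] <- GENE_ALIASES[hit[!is.na(hit)]]
  name
}

name_prefix <- function(name) sub("^([A-Za-z]+).*$", "\\1", name)

#' Construct and validate a kinase interaction edge list
#'
#' @param edges Data frame with columns `upstream`, `downstream`, `tier`
#'   (`KKK-KK` or `KK-K`) and optional `source`. Tier must agree with
#'   name prefixes (KKK-KK: MEKK/ANP/YDA/RAF/CTR/EDR/ZIK -> MKK; KK-K:
#'   MKK -> MPK); duplicates are rejected. Names are normalized via
#'   [normalize_gene_name()].
#' @return Validated data frame with class `interaction_edges`.
#' @export
interaction_edges <- function(edges) {
  need <- c("upstream", "downstream", "tier")
  missing_cols <- setdiff(need, names(edges))
  if (length(missing_cols))
    stop("edge list lacks column(s): ", paste(missing_cols, collapse = ", "))
  edges$upstream <- normalize_gene_name(edges$upstream)
  edges$downstream <- normalize_gene_name(edges$downstream)
  if (is.null(edges$source))
    edges$source <- rep(NA_character_, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    up <- toupper(name_prefix(edges$upstream[i]))
    dn <- toupper(name_prefix(edges$downstream[i]))
    tier <- edges$tier[i]
    ok <- switch(tier,
                 "KKK-KK" = up %in% KKK_PREFIXES && dn == "MKK",
                 "KK-K"   = up == "MKK" && dn == "MPK",
                 stop("unknown tier '", tier, "' in row ", i))
    if (!ok)
      stop("tier/prefix mismatch in row ", i, ": ", edges$upstream[i],
           " -> ", edges$downstream[i], " labelled ", tier)
  }
  if (anyDuplicated(edges[need]))
    stop("duplicate interaction edge(s): ",
         paste(which(duplicated(edges[need])), collapse = ", "))
  structure(edges[c(need, "source")], class = c("interaction_edges",
                                                "data.frame"))
}

#' Build the tripartite cascade graph from interaction edges
#'
#' Assembles a three-layer directed graph (MAPKKK, MKK, MAPK) as an
#' igraph object with a `tier` vertex attribute, after name
#' normalization.
#'
#' @param edges An [interaction_edges()] data frame (or raw data frame).
#' @return List of class `cascade_graph`: `graph` (igraph), `edges`,
#'   `layers` (node names per tier), `summary` (per-layer node counts and
#'   per-node degrees).
#' @export
build_graph <- function(edges) {
  if (!inherits(edges, "interaction_edges")) edges <- interaction_edges(edges)
  kkk_kk <- edges[edges$tier == "KKK-KK", ]
  kk_k <- edges[edges$tier == "KK-K", ]
  layers <- list(
    KKK = sort(unique(kkk_kk$upstream)),
    KK = sort(unique(c(kkk_kk$downstream, kk_k$upstream))),
    K = sort(unique(kk_k$downstream)))
  nodes <- data.frame(
    name = c(layers$KKK, layers$KK, layers$K),
    tier = rep(c("KKK", "KK", "K"), lengths(layers)),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[c("upstream", "downstream", "tier")],
    directed = TRUE, vertices = nodes)
  structure(list(
    graph = g, edges = edges, layers = layers,
    summary = list(
      n_nodes = lengths(layers),
      n_edges = c(`KKK-KK` = nrow(kkk_kk), `KK-K` = nrow(kk_k)),
      in_degree = igraph::degree(g, mode = "in"),
      out_degree = igraph::degree(g, mode = "out"))),
    class = "cascade_graph")
}

#' Enumerate complete MAPKKK-MKK-MAPK cascade modules
#'
#' Every (KKK, KK, K) triple with both tier edges present and no member
#' in the exclusion set. Excluded genes are removed from the graph
#' before enumeration. Modules are ordered deterministically by
#' numeric-aware lexicographic (kkk, kk, k).
#'
#' @param graph A [build_graph()] result (or an edge data frame).
#' @param exclusions Character vector of gene names to drop (display
#'   aliases accepted).
#' @return Data frame with columns `kkk`, `kk`, `k`.
#' @export
#' @examples
#' fx <- load_cotton_fixtures()
#' nrow(enumerate_modules(build_graph(fx$edges), fx$exclusions$gene))  # 38
enumerate_modules <- function(graph, exclusions = character()) {
  if (!inherits(graph, "cascade_graph")) graph <- build_graph(graph)
  exclusions <- normalize_gene_name(exclusions)
  e <- graph$edges
  e <- e[!(e$upstream %in% exclusions | e$downstream %in% exclusions), ]
  kkk_kk <- e[e$tier == "KKK-KK", c("upstream", "downstream")]
  kk_k <- e[e$tier == "KK-K", c("upstream", "downstream")]
  names(kkk_kk) <- c("kkk", "kk")
  names(kk_k) <- c("kk", "k")
  modules <- merge(kkk_kk, kk_k, by = "kk")[c("kkk", "kk", "k")]
  modules <- modules[gene_order(modules$kkk, modules$kk, modules$k), ,
                     drop = FALSE]
  rownames(modules) <- NULL
  modules
}

#' Annotate cascade modules with shared stress responses
#'
#' For each module, intersects the induced-treatment sets of the members
#' that have a response profile; members without a profile are skipped
#' and counted in `n_profiled`. The intersection is split into the
#' signal family (JA, H2O2, ABA, SA) and the abiotic family (NaCl, PEG,
#' cold, heat, wounding).
#'
#' @param modules Data frame from [enumerate_modules()].
#' @param profiles Data frame with columns `gene`, `treatment` (long
#'   format: one row per induced gene x treatment) and optional
#'   `provenance`.
#' @return `modules` with added columns `shared_signal`, `shared_abiotic`
#'   (comma-separated treatment sets), `n_profiled` (members with a
#'   profile, 0-3) and `low_support` (TRUE when fewer than 2 members have
#'   profiles).
#' @export
annotate_shared_responses <- function(modules, profiles) {
  profiles$gene <- normalize_gene_name(profiles$gene)
  prof_sets <- split(as.character(profiles$treatment), profiles$gene)
  profiled_genes <- names(prof_sets)
  annotate_one <- function(members) {
    have <- members[members %in% profiled_genes]
    shared <- if (length(have) == 0L) character() else
      Reduce(intersect, prof_sets[have])
    list(signal = intersect(SIGNAL_TREATMENTS, shared),
         abiotic = intersect(ABIOTIC_TREATMENTS, shared),
         n = length(have))
  }
  ann <- lapply(seq_len(nrow(modules)), function(i)
    annotate_one(c(modules$kkk[i], modules$kk[i], modules$k[i])))
  modules$shared_signal <- vapply(ann, function(a)
    paste(a$signal, collapse = ","), character(1L))
  modules$shared_abiotic <- vapply(ann, function(a)
    paste(a$abiotic, collapse = ","), character(1L))
  modules$n_profiled <- vapply(ann, function(a) as.integer(a$n), integer(1L))
  modules$low_support <- modules$n_profiled < 2L
  modules
}

#' Summarize a kinase interaction edge list
#'
#' @param edges An [interaction_edges()] data frame (or raw data frame).
#' @return List: `n_pairs` per tier, `kkk_subfamily_pairs` (KKK-KK pairs
#'   split by MAPKKK subfamily), `n_nodes` per layer, and `mkk_partners`
#'   (per-MKK upstream/downstream partner lists).
#' @export
summarize_interactions <- function(edges) {
  if (!inherits(edges, "interaction_edges")) edges <- interaction_edges(edges)
  kkk_kk <- edges[edges$tier == "KKK-KK", ]
  kk_k <- edges[edges$tier == "KK-K", ]
  fams <- if (nrow(kkk_kk)) subfamily_from_name(kkk_kk$upstream) else
    character()
  fam_counts <- table(factor(fams, levels = c("MEKK", "Raf", "ZIK")))
  mkks <- sort(unique(c(kkk_kk$downstream, kk_k$upstream)))
  list(
    n_pairs = c(`KKK-KK` = nrow(kkk_kk), `KK-K` = nrow(kk_k)),
    kkk_subfamily_pairs = setNames(as.integer(fam_counts), names(fam_counts)),
    n_nodes = c(KKK = length(unique(kkk_kk$upstream)),
                KK = length(mkks),
                K = length(unique(kk_k$downstream))),
    mkk_partners = setNames(lapply(mkks, function(m) list(
      upstream = sort(kkk_kk$upstream[kkk_kk$downstream == m]),
      downstream = sort(kk_k$downstream[kk_k$upstream == m]))), mkks))
}

#' Export a cascade graph as a DOT file
#'
#' @param graph A [build_graph()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  stopifnot(inherits(graph, "cascade_graph"))
  e <- graph$edges
  lines <- c("digraph mapk_cascades {", "  rankdir=LR;",
             sprintf("  \"%s\" -> \"%s\";", e$upstream, e$downstream), "}")
  writeLines(lines, path)
  invisible(path)
}
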