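# Minimal OBO reader/writer for GO term stanzas.  Only the fields the DAG
# model needs are handled: id, name, namespace, is_a, is_obsolete.

oboNamespaceMap <- c(molecular_function = "MF",
                     biological_process = "BP",
                     cellular_component = "CC")

# Parse an OBO file into list(terms = data.frame(id, name, domain),
# edges = data.frame(child, parent)).  Obsolete terms are dropped together
# with their edges.
parseObo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    end <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[(starts[i] + 1L):end]
    field <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
      trimws(sub(paste0("^", tag, ":"), "", hit))
    }
    id <- field("id")
    if (length(id) != 1L) next
    if (any(field("is_obsolete") == "true")) next
    ns <- field("namespace")
    dom <- if (length(ns)) unname(oboNamespaceMap[ns[1L]]) else NA_character_
    if (is.na(dom))
      stop("OBO term ", id, " has unknown or missing namespace")
    nm <- field("name")
    parents <- sub("\\s*!.*$", "", field("is_a"))
    terms[[length(terms) + 1L]] <-
      data.frame(id = id, name = if (length(nm)) nm[1L] else id,
                 domain = dom, stringsAsFactors = FALSE)
    if (length(parents))
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = parents, stringsAsFactors = FALSE)
  }
  terms <- if (length(terms)) do.call(rbind, terms)
    else data.frame(id = character(), name = character(), domain = character())
  edges <- if (length(edges)) do.call(rbind, edges)
    else data.frame(child = character(), parent = character())
  # drop edges pointing at obsolete/unknown terms
  edges <- edges[edges$parent %in% terms$id & edges$child %in% terms$id, ,
                 drop = FALSE]
  list(terms = terms, edges = edges)
}

# Write a term table + edge list as a minimal OBO file (used by the fixture
# generator so that readGODag() can consume its own bundles).
writeObo <- function(terms, edges, path) {
  rev <- setNames(names(oboNamespaceMap), oboNamespaceMap)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(terms))) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", terms$id[i]), con)
    writeLines(paste0("name: ", terms$name[i]), con)
    writeLines(paste0("namespace: ", rev[[terms$domain[i]]]), con)
    for (p in edges$parent[edges$child == terms$id[i]])
      writeLines(paste0("is_a: ", p), con)
    writeLines("", con)
  }
  invisible(path)
}
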