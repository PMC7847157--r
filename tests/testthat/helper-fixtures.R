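# Small programmatic fixtures shared across test files.

net_from_edges <- function(..., species = "s1", nodes = NULL) {
  pairs <- list(...)
  edges <- tibble::tibble(
    from = vapply(pairs, `[[`, "", 1L),
    to   = vapply(pairs, `[[`, "", 2L)
  )
  funalign::ppi_network(edges, species, nodes = nodes, quiet = TRUE)
}

toy_nets <- function() {
  list(
    n1 = net_from_edges(c("a", "b"), c("b", "c"), species = "y"),
    n2 = net_from_edges(c("x", "w"), c("w", "z"), c("z", "v"), species = "h",
                        nodes = c("x", "w", "z", "v"))
  )
}

toy_annotations <- function() {
  funalign::annotation_set(tibble::tribble(
    ~protein, ~term,        ~evidence, ~aspect,
    "a",      "GO:0000001", "EXP",     "P",
    "a",      "GO:0000002", "IDA",     "P",
    "b",      "GO:0000001", "IMP",     "P",
    "c",      "GO:0000009", "EXP",     "P",
    "x",      "GO:0000001", "EXP",     "P",
    "x",      "GO:0000002", "IGI",     "P",
    "w",      "GO:0000002", "IEA",     "P",   # electronic only
    "z",      "GO:0000005", "EXP",     "C",   # wrong aspect
    "c",      "GO:0000005", "EXP",     "C",
    "v",      "GO:0000009", "EXP",     "P"
  ))
}

# deterministic small world with clear signal, reused by pipeline tests
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- funalign::generate_world(funalign::synth_config(
        n_modules = 5L, module_size = c(4L, 5L), background_nodes = 15L,
        seed = 42L))
    }
    cache
  }
})

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
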