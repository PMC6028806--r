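## ---------------------------------------------------------------------------
## Native model dialect: line-oriented, tab-separated, one entity per record.
## Diffable and hand-writable; numbers carried to 17 significant digits so a
## round trip is exact to well beyond 12 digits.
##
##   # comment
##   model        <name>
##   solver       ode_stiff | ode_nonstiff | hh
##   compartment  <name> <volume litres>
##   group        <path>
##   pool         <path> <compartment> <concInit mM> <buffered 0|1>
##   reaction     <path> <Kf> <Kb> <subs path:stoich,...> <prods path:stoich,...>
##   enzyme       <path> <enzymePool> <substrate> <product> <Km mM> <kcat /s>
##   hh           <param> <value>      (Hodgkin-Huxley block, solver 'hh')
## ---------------------------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

parse_stoich_list <- function(s, where) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  out <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop_expsim("%s: malformed stoichiometry entry '%s'", where, p)
    out[kv[[1]]] <- as.numeric(kv[[2]])
  }
  out
}

fmt_stoich_list <- function(v)
  paste(sprintf("%s:%s", names(v), fmt_num(v)), collapse = ",")

#' Read a model in the native text dialect
#' @param path file path
#' @return a `ReactionModel` (not yet validated; see [load_model()])
#' @export
read_native_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  model <- new_reaction_model()
  model$compartments <- list()
  hh <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    rec <- f[[1]]
    where <- sprintf("%s:%d", path, i)
    need <- function(n) if (length(f) < n + 1L)
      stop_expsim("%s: record '%s' needs %d fields", where, rec, n)
    switch(rec,
      model = { need(1); model$name <- f[[2]] },
      solver = { need(1); model$solver <- f[[2]] },
      compartment = { need(2)
        model <- add_compartment(model, f[[2]], as.numeric(f[[3]])) },
      group = { need(1); model <- add_group(model, f[[2]]) },
      pool = { need(4)
        model <- add_pool(model, f[[2]], concInit = as.numeric(f[[4]]),
                          buffered = f[[5]] == "1", compartment = f[[3]]) },
      reaction = { need(5)
        model <- add_reaction(model, f[[2]],
                              substrates = parse_stoich_list(f[[5]], where),
                              products   = parse_stoich_list(f[[6]], where),
                              Kf = as.numeric(f[[3]]), Kb = as.numeric(f[[4]])) },
      enzyme = { need(6)
        model <- add_enzyme(model, f[[2]], enzymePool = f[[3]],
                            substrate = f[[4]], product = f[[5]],
                            Km = as.numeric(f[[6]]), kcat = as.numeric(f[[7]])) },
      hh = { need(2); hh[[f[[2]]]] <- as.numeric(f[[3]]) },
      stop_expsim("%s: unknown record type '%s'", where, rec)
    )
  }
  if (length(hh)) model$hh <- do.call(hh_compartment, hh)
  model
}

#' Write a model in the native text dialect
#' @param model a `ReactionModel`
#' @param dest destination file path
#' @export
write_native_model <- function(model, dest) {
  out <- c("# expsim native model v1",
           paste("model", model$name, sep = "\t"),
           paste("solver", model$solver, sep = "\t"))
  for (cm in model$compartments)
    out <- c(out, paste("compartment", cm$name, fmt_num(cm$volume), sep = "\t"))
  for (g in model$groups)
    out <- c(out, paste("group", g, sep = "\t"))
  for (p in model$pools)
    out <- c(out, paste("pool", p$path, p$compartment, fmt_num(p$concInit),
                        if (p$buffered) "1" else "0", sep = "\t"))
  for (r in model$reactions)
    out <- c(out, paste("reaction", r$path, fmt_num(r$Kf), fmt_num(r$Kb),
                        fmt_stoich_list(r$substrates),
                        fmt_stoich_list(r$products), sep = "\t"))
  for (e in model$enzymes)
    out <- c(out, paste("enzyme", e$path, e$enzymePool, e$substrate, e$product,
                        fmt_num(e$Km), fmt_num(e$kcat), sep = "\t"))
  if (!is.null(model$hh))
    for (nm in names(model$hh))
      out <- c(out, paste("hh", nm, fmt_num(model$hh[[nm]]), sep = "\t"))
  writeLines(out, dest, useBytes = TRUE)
  invisible(dest)
}
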