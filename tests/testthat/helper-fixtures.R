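# Shared fixtures, built once per test run and memoized: small icospheres,
# their graphs/areas/kernels, and a compact two-group phantom cohort.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

ico2 <- function() fixture("ico2", function() icosphere(2, 50))
ico3 <- function() fixture("ico3", function() icosphere(3, 50))
ico2_graph <- function() fixture("ico2_graph", function() mesh_graph(ico2()))
ico3_graph <- function() fixture("ico3_graph", function() mesh_graph(ico3()))
ico3_areas <- function() fixture("ico3_areas", function() vertex_areas(ico3()))
ico3_kernel15 <- function() fixture("ico3_kernel15", function()
  smoothing_kernel(ico3(), 15, ico3_graph()))

default_phantom <- function() fixture("default_phantom", function() phantom_spec())

# 30 patients vs 30 controls on the default phantom with the default
# core/halo/thickness-only effect structure.
dissociation_cohort <- function() fixture("dissociation_cohort", function() {
  phantom <- default_phantom()
  mesh <- make_surface_pair(phantom)$white
  eff <- default_effect(mesh, graph = ico3_graph())
  des <- cohort_design(n_control = 30, n_nfvppa = 30, n_svppa = 0,
                       n_lvppa = 0, n_ppa_grn = 0)
  sim <- simulate_cohort(des, phantom, eff, site_effect_spec(), seed = 11)
  list(sim = sim, mesh = mesh, effect = eff)
})

with_seed_perm <- function(x, seed) {
  set.seed(seed)
  sample(x)
}

# Expand a vertex set by one edge ring (used for nesting checks with
# boundary tolerance).
expand_one_ring <- function(mesh, verts) {
  e <- mesh_edges(mesh)
  sort(unique(c(verts,
                e[e[, 1L] %in% verts, 2L],
                e[e[, 2L] %in% verts, 1L])))
}

# Independent flood-fill component labeling oracle on a vertex subset.
flood_fill_components <- function(mesh, verts) {
  e <- mesh_edges(mesh)
  keep <- e[, 1L] %in% verts & e[, 2L] %in% verts
  adj <- list()
  for (v in verts) adj[[as.character(v)]] <- integer(0)
  for (r in which(keep)) {
    a <- as.character(e[r, 1L]); b <- as.character(e[r, 2L])
    adj[[a]] <- c(adj[[a]], e[r, 2L])
    adj[[b]] <- c(adj[[b]], e[r, 1L])
  }
  seen <- character(0)
  comps <- list()
  for (v in verts) {
    if (as.character(v) %in% seen) next
    queue <- v
    comp <- integer(0)
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      cu <- as.character(u)
      if (cu %in% seen) next
      seen <- c(seen, cu)
      comp <- c(comp, u)
      queue <- c(queue, adj[[cu]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
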