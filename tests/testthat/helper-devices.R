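# shared fixtures and generators for the test suite

metoprolol <- function() tdds_fixture("metoprolol_tdds1")
ata <- function() tdds_fixture("ata_tdds2")

# realise a (beta, p, km) triple as a dimensional device with lb = D2 = 1:
# beta * p = lb/la fixes la, and beta = D2 la / (D1 lb) fixes D1
device_from_groups <- function(beta, p, km,
                               kind = c("reservoir", "matrix"), C0 = 1) {
  la <- 1 / (beta * p)
  tdds_device(match.arg(kind),
    D1 = la / beta, D2 = 1, la = la, lb = 1,
    km = km, C0 = C0, time_unit = "s"
  )
}

# log-uniform (beta, p, km) triples over the tested envelope
random_triples <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    beta = 10^stats::runif(n, -3, 3),
    p = 10^stats::runif(n, -2, 3),
    km = 10^stats::runif(n, -2, 2)
  )
}

# discrete first moment of the approach to steady state, reused by the
# three-way identity tests (hours)
pde_moment_hours <- function(device, n = 100L, nt = 3000L, window = 14) {
  sol <- solve_pde(device, grid = pde_grid(
    n1 = n, n2 = n, nt = nt,
    window = window
  ))
  tdds:::pde_effective_time(sol)
}
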