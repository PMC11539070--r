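# Shared toy fixtures, built in code at test time.

toy_grid <- function(n = 4, lo = -0.02, hi = 0.02) seq(lo, hi, length.out = n)

toy_profile <- function(grid, areas, volume = 100) {
  sigma_profile(grid, areas, cavity_area = sum(areas), cavity_volume = volume)
}

toy_compound <- function(name, grid, areas, volume = 100, V = 80, mw = 120,
                         tm = 150) {
  compound(name, toy_profile(grid, areas, volume), molar_volume = V,
           melting_point = tm, state_flag = "solid", molecular_weight = mw)
}

# fast engine settings for toys (tight tolerance, generous iteration cap)
toy_params <- function(...) cosmo_parameters(...)

# donor-only / acceptor-only pair on a small grid: hydrogen-bond
# complementary by construction
toy_donor_acceptor_pair <- function() {
  g <- seq(-0.02, 0.02, by = 0.01)           # 5 bins
  donor <- toy_compound("donor", g, c(30, 0, 70, 0, 0), volume = 110)
  acceptor <- toy_compound("acceptor", g, c(0, 0, 70, 0, 30), volume = 110)
  list(donor = donor, acceptor = acceptor)
}
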