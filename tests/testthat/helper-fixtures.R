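# shared fixtures, built in code at load time

# constant 0-permil atmosphere: pools sit at their closed-form steady state
flat_curve <- function(last_year = 2025) {
  load_curve(data.frame(year = c(1900, last_year),
                        delta14c_permil = c(0, 0)),
             label = "flat 0 permil")
}

default_curve <- synthetic_bomb_curve()

# Delta14C (sample convention) a pool at fraction modern F shows in `year`
fm_to_d14c <- function(f, year) (f * exp((1950 - year) / 8267) - 1) * 1000
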