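---
title: "Modelling microbial biomass production in hydrothermal plumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microbial biomass production in hydrothermal plumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumeMTS)
```

This vignette is the package's own account of the science it implements:
the model chain, its assumptions, the parameters that matter, the numerical
choices, and what the synthetic study conditions do and do not show about
real plumes.

## 1. The rising plume

A black smoker discharges hot (300–400 °C), buoyant fluid into a stratified
water column. We solve the classical top-hat conservation equations for
specific volume flux $q = u r^2$, momentum flux $m = u^2 r^2$ and buoyancy
flux $F = g\,(\rho_a - \rho)\,q/\rho_{ref}$:

$$\frac{dq}{dz} = 2 \alpha_e \sqrt{m}, \qquad
  \frac{dm}{dz} = \frac{F q}{m}, \qquad
  \frac{dF}{dz} = -N^2 q,$$

with the Boussinesq approximation and a linearly stratified ambient of
buoyancy frequency $N^2 = (g/\rho_{ref})(\rho_{site}-\rho_{ref})/\Delta z$.
The governing equations are often written for a uniform environment, but a
neutral-buoyancy level only exists under stratification; integrating the
deficit flux against a linear ambient recovers the uniform case exactly when
$N^2 = 0$, which is how the self-similar test regime is built.

Entrainment interpolates between the jet and plume regimes through the local
Froude number, $\alpha_e = \alpha_j - (\alpha_j-\alpha_p)(Fr_p/Fr)^2$,
clamped to $[\alpha_j, \alpha_p]$. Defaults $\alpha_j = 0.08$,
$\alpha_p = 0.16$, $Fr_p = 1.6$ sit mid-range of the observationally
supported jet (0.05–0.10) and plume (0.15–0.20) bands; all three are
arguments of `integrate_plume()`. Against the classical maximum-rise formula
$z_{max} = 3.76\,F_0^{1/4} N^{-3/4}$ (with $F_0$ in the volume-flux
convention, i.e. including the $\pi r^2$ factor) these defaults land within
about 7% — comfortably inside the 15% scatter of the empirical constant.

Termination ("the NBP"): the first height where the plume is negatively
buoyant *and* the vertical velocity has decayed below 1% of its running
maximum, i.e. essentially the maximum rise height, detected by a root
function on the adaptive integration (relative tolerance $10^{-8}$, two
passes: root search, then a clean 300-cell output grid). The dilution
reported for chemistry is the volume-flux ratio $q(z_{NBP})/q_0$ — there is
no single standard convention for collapsing per-cell dilution ratios into
one NBP dilution, and the volume-flux ratio is the one consistent with
conservative scalar mixing.

Seawater density uses the EOS-80 polynomial (surface term plus secant bulk
modulus), linearized above 40 °C where the polynomial leaves its fitted
range. A 360 °C end-member is therefore too dense in the model by a few
hundred kg m⁻³; this only compresses the first metres of rise because
entrainment restores near-ambient temperature almost immediately, and the
rise-height oracle test bounds the residual effect.

## 2. Gibbs energies

Formation energies at 25 °C / 1 bar are embedded as a versioned CSV table
(aqueous standard states from standard compilations; goethite and pyrolusite
for the Fe/Mn oxide products; biomass at −67 kJ per C-mol). In-situ
temperature correction uses Gibbs–Helmholtz with $\Delta C_p = 0$:
$\Delta G_f(T) = \Delta G_f(T_0)\,T/T_0 + \Delta H_f(T_0)(1 - T/T_0)$.
Pressure corrections are off by default: at 2–4 °C and 150–400 bar the
molar-volume terms are of order a few kJ mol⁻¹, negligible against
dissipation energies of 500–3500 kJ molC⁻¹. Because pyrolusite is in the
table, the Mn-oxidation energy is computed like every other reaction; a
per-guild `dG_cat0_override` remains available for users who prefer a
literature constant.

Activities: concentrations (mol m⁻³) convert to molality via
1 m³ ≈ 10³ kg solvent; charged aqueous species get Davies coefficients
($A = 0.509$, seawater ionic strength $I \approx 0.0199\,S$), neutral
solutes 1, solids and biomass 1, and water $a_w = 1 - 0.000537\,S$. Davies
is stretched at $I = 0.7$ mol kg⁻¹ but errs by far less than the spread of
the dissipation energies; a `unit` mode exists so balance and limit tests
are activity-independent, and a B-dot variant is provided.

## 3. The 18-guild community model

Each guild is one metabolism: a catabolic reaction normalized to consume
exactly one mole of electron donor and an anabolic reaction normalized to
produce one C-mole of biomass ($CH_{1.8}O_{0.5}N_{0.2}$). The overall
metabolism is $A_{met} = A_{ana} + A_{cat}\,\mathrm{diag}(\lambda)$ with
$\lambda_g = -(\Delta G_{ana} + \Delta G_{diss})/\Delta G_{cat}$, recomputed
with current activities at every solver step; a non-exergonic catabolism
deactivates its guild.

Two tabulated anabolisms do not close elementally as printed and are
corrected: the Mn oxidizer consumes 2.1 Mn²⁺ (matching its 2.1 MnO₂
product), and nitritation gains 0.7 NO₂⁻ on the product side (restoring N
and charge closure). The test suite asserts both the corrected balance and
the failure of the printed forms. The iron oxidizer keeps FeOOH as catabolic
product and Fe³⁺ as anabolic product, exactly as tabulated.

Dissipation energies: the Heijnen correlation for acetate (chain length 2,
degree of reduction 8) gives 1477 kJ molC⁻¹, but empirical values are used
per trophic class — 539 kJ molC⁻¹ for aerobic acetate respiration,
557 kJ molC⁻¹ for acetate denitrification (the published heterotrophic range
is 539–557 without per-guild attribution; assigning the lower value to the
higher-yield aerobic pathway is the configurable default), and a single
3500 kJ molC⁻¹ for all 16 chemolithoautotrophic guilds, representing the
average cost including reverse electron transport.

Growth follows the MTS multi-substrate law
$\mu = \mu_{max} \prod_i \exp(A_{met,i}/(V_{harv}[S_i]))$ over consumed
species, $\mu_{max} = k_B T / h_P$. Water and protons are excluded from the
product: their bulk "concentrations" (55 mol kg⁻¹; pH-level H⁺) carry no
information about substrate scarcity and would otherwise dominate
meaninglessly. The harvest volume $V_{harv} = 1000$ m³ per mol biomass is
the single most influential parameter (see the sensitivity sweep below).

Mortality is first order ($\alpha = 1.16\times10^{-8}$ s⁻¹, uniform across
guilds) with the dead carbon split 40% labile DOC / 10% refractory DOC /
50% POC. Labile DOC is carried as acetate-carbon (2 C per molecule) so it
feeds the two heterotrophic guilds; biomass N returns as NH₄⁺ and H/O close
on water. Exact closure then forces a nominal composition
$CH_{4/3}O_{1/2}$ on the two inert pools (with 0.2 H₂O consumed per C-mol
of dead biomass) — the pools never react, so this composition affects only
elemental bookkeeping, but it lets every mortality column pass the same
1e-6 balance check as the metabolic columns.

State: 23 chemical species plus 18 biomasses. The published species count
is quoted inconsistently (21 in one place, 27 in another); the 23-species
registry is a reconstruction covering every species referenced by the 36
reactions plus the two inert pools, and is user-replaceable via CSV.

Initial biomass: $10^5$ cells ml⁻¹ × 20 fgC cell⁻¹ (a standard deep-sea
prokaryote quota; the source material is silent on the conversion)
= $1.67\times10^{-4}$ molC m⁻³, split uniformly across guilds.

### Numerics

`deSolve::lsoda` with rtol $10^{-8}$, atol $10^{-15}$ mol m⁻³. When labile
substrate exceeds the MTS activation threshold the consumption transient is
violent (µ can transiently reach $10^6$ s⁻¹ before the substrate relaxes
onto the threshold), so the system is integrated in flux form with
concentrations floored at zero inside the rate evaluation only; negative
excursions stay within the absolute tolerance, and closed-system carbon is
conserved to ~$10^{-14}$ relative over 30 days (asserted at $10^{-6}$ per
simulated day). Production is reported from the biomass trajectory as
$X(T) - X(0) + \alpha\int X\,dt$ rather than by sampling $\mu$, which makes
the reported rates insensitive to the unresolved sharpness of the initial
transient. PHP (prokaryotic heterotrophic production) is the time-averaged
gross anabolic carbon flux into the two chemoorganotrophic guilds
(µgC L⁻¹ d⁻¹ = molC m⁻³ s⁻¹ × 12.011 × 86400 × 10³); "gross" is adopted
because positive catabolic activity coexists with zero-or-negative *net*
autotrophic production, which a net convention would hide.

## 4. Budget arithmetic

Heterotrophic production saturates with per-vent heat flux as
$HP(Q) = a\,Q/(K+Q)$ ($a = 0.0123$ µgC L⁻¹ d⁻¹, $K = 5.987$ MW). Its mean
over the global vent heat flux uses the analytic primitive
$aQ - aK\ln(Q+K)$ between $Q_{sw}$ and $Q_{vents}$. $Q_{sw} = 0.001$ is
interpreted in MW (the curve's abscissa unit); the integral is insensitive
to this choice at the reported precision, and both bound parameters are
arguments. Areal production converts the volumetric rate through a 200 m
plume layer (× 10⁻³ × height × 365 → gC m⁻² y⁻¹); global production
multiplies by vent counts (1305, range 713–1853) and plume footprints
(1000 km², optionally 10% at 400×10³ km²). The published "average"
volumetric rate (0.01235) is not the arithmetic mean of the tabulated site
rates (0.00998); the package therefore exposes both the site-table mean and
the heat-flux-integral average, and the budget functions take the rate as
an explicit argument.

## 5. Synthetic study conditions

`site_template()`/`generate_site()` draw literature-plausible black-smoker
sites: 300–400 °C, 0.1–2 m s⁻¹, 5–30 cm orifices, 1500–4000 m depth,
mol m⁻³-level sulfide/hydrogen/methane/iron/manganese end-members
(log-uniform), deep stratification $N^2 = 10^{-7}$–$10^{-6}$ s⁻². They are
stand-ins, not reconstructions of any real site; one hand-written TAG-like
site ships as a stable, human-readable fixture (labelled synthetic in its
filename).

The background labile DOC deserves a note. Total deep-sea DOC is ~40 µM-C
but overwhelmingly refractory; the labile acetate pool that actually feeds
heterotrophs is nanomolar. The MTS activation threshold at deep-sea
temperature and $V_{harv} = 1000$ m³ molC⁻¹ sits near
$5\times10^{-5}$ molC m⁻³ of acetate-carbon, and observed bathypelagic PHP
(2–6 × 10⁻³ µgC L⁻¹ d⁻¹) is consistent with a labile pool just above that
threshold. The background is therefore fixed at $10^{-4}$ molC m⁻³ labile
acetate-C (0.1 µM-C) with the 40 µM-C bulk carried in the inert refractory
pool. With it, the model yields 0.0071 µgC L⁻¹ d⁻¹ for background seawater
and 0.0090 for the TAG-like fixture plume — the same structure as the
published site compilation (plume above seawater, all rates within the
0.009–0.012 band, no net chemolithoautotrophy) without using any real site
data.

What passing tests show — and don't. The synthetic conditions exercise every
code path (plume solve, fallback dilution, activation and starvation of
guilds, recycling) and reproduce the qualitative regime structure of real
plumes. They do not validate end-member compositions of real vent fields,
abiotic sulfide/iron oxidation in the rising plume (deliberately ignored;
the override mechanism `apply_overrides()` exists to splice in measured NBP
concentrations), crossflow-bent plumes, or mesoscale transport.

## 6. Problem sizes

The routine test suite runs 30-day community integrations at 301 output
points, a 10-site synthetic pipeline batch, 200-replicate Monte-Carlo curve
recovery, and 200-draw generator property checks — about 15–20 s in total;
the 100-site closure experiment reported during development behaves
identically and is kept out of the default suite in favour of the 10-site
batch.

## 7. Known limitations

- No speciation/complexation equilibria or pH buffering: H⁺ is a
  conservative explicit species, so plume pH is approximate.
- No HKF-style T/P extrapolation of formation energies; Gibbs–Helmholtz
  only, pressure off by default.
- Dilution-only NBP chemistry (no abiotic reaction during rise).
- Guild set and ΔG_diss values are fixed per metabolism: no mixotrophy or
  C-fixation-pathway switching.
- The exponential MTS growth law makes site rates extremely sensitive to
  labile substrate near the activation threshold — orders of magnitude per
  factor-of-two in [S]. Conclusions should be read at the
  order-of-magnitude level the budget arithmetic actually uses.
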