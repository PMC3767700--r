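# Bundled material table.
# water/nickel/silicon/gold: physical densities and (Z_sum, formula mass).
# Soft-tissue rows are SYNTHETIC defaults for phantom construction: electron
# densities set within a few percent of water (via a water-like Z/A and a
# scaled density) and mu values are plausible constants near 23 keV, chosen
# so relative vessel-layer contrast is larger in delta than in mu. They are
# simulation parameters, not measured tissue values.
name,mass_density_g_cm3,electrons_per_unit,mass_per_unit_g_mol,mu_per_m,mu_energy_kev
water,1.000,10,18.015,57.0,23
background_fluid,1.000,10,18.015,57.0,23
intima,1.030,10,18.015,57.6,23
media,1.045,10,18.015,57.9,23
adventitia,1.020,10,18.015,57.4,23
lipid_core,0.920,10,18.015,53.0,23
fibrous_cap,1.040,10,18.015,57.8,23
calcification,1.550,10,18.015,240.0,23
air,0.0012,14.4,28.96,0.06,23
nickel,8.908,28,58.69,42000,23
silicon,2.329,14,28.085,215,23
gold,19.30,79,196.97,710000,23
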