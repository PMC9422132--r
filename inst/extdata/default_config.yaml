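# Default constants for the headline reproduction. Units in key names.
morphometry:
  length_um: 1.71            # microvillus length
  base_radius_um: 0.06       # cylindrical base radius
  tip_radius_um: 0.12        # bulbous tip radius (not used by default)
  density_per_um2: 18        # microvilli per um^2 bulk membrane
  brush_border_extent_um: 1.5  # effective brush-border depth = channel length
tissue:
  epithelium_mass_mg: 4.6    # wet mass, lateral + 4th choroid plexus
  cell_density_g_per_cm3: 1.0
  cell_height_um: 10
physiology:
  vp_ul_min: 6.8             # observed CSF secretion rate
  slope_ul_min_mosm: 0.023   # osmotic-challenge regression slope
  plasma_osm_mosm: 306
  csf_osm_mosm: 307
  csf_density_g_ml: 1.00
  lp_trans_published: null   # set to 8.7e-5 to use the published value
model:
  diffusion_cm2_s: 1.5e-5    # NaCl in water at 37 C
  reflection_coeff: 1.0
  partial_molar_vol_water_cm3_mol: 18
windows:
  baseline_min: [50, 65]
  treatment_min: [100, 120]
  osmotic_min: [50, 75]
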