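# Default three-pore membrane constants. These are standard literature
# values for the human peritoneal membrane; every entry can be overridden
# through pore_system(). Units noted per field.
alpha:            # fraction of total hydraulic conductance per pathway
  ultrasmall: 0.02
  small: 0.90
  large: 0.08
r_small: 43       # small-pore radius, Angstrom
r_large: 250      # large-pore radius, Angstrom
LpS: 0.074        # total hydraulic conductance, mL/(min*mmHg)
dP: 8             # capillary-to-cavity hydrostatic pressure difference, mmHg
pi_p: 22          # plasma colloid osmotic pressure, mmHg
RT: 19.3          # osmotic conversion at 310 K, mmHg per (mmol/L)
protein_radius: 36   # effective albumin radius, Angstrom (sets sigma_protein)
solute_radii:     # effective solute radii, Angstrom
  urea: 2.6
  creatinine: 3.0
  glucose: 3.7
  sodium: 2.3
  potassium: 2.2
  phosphate: 3.3
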