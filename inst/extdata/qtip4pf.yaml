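# q-TIP4P/F flexible water model constants, in package-internal units
# (nm, amu, ps, kJ/mol). Source: Habershon, Markland & Manolopoulos,
# J. Chem. Phys. 131, 024501 (2009), Table I, converted from
# kcal/mol and Angstrom.
D_r: 485.72056        # Morse well depth D_r = 116.09 kcal/mol
alpha_r: 22.87        # Morse range alpha_r = 2.287 1/Angstrom
r_eq: 0.09419         # OH equilibrium bond length 0.9419 Angstrom
k_theta: 367.5644     # HOH angle force constant 87.85 kcal/mol/rad^2
theta_eq: 1.8744836   # HOH equilibrium angle 107.4 degrees
epsilon_LJ: 0.7748768 # O-O Lennard-Jones epsilon = 0.1852 kcal/mol
sigma_LJ: 0.31589     # O-O Lennard-Jones sigma = 3.1589 Angstrom
q_H: 0.5564           # hydrogen charge, e (M site carries -2 q_H)
gamma_M: 0.73612      # M-site weight: r_M = g r_O + (1-g)/2 (r_H1 + r_H2)
m_O: 15.9994          # oxygen mass, amu
m_H: 1.008            # hydrogen mass, amu
r_c: 1.0              # nonbonded cutoff, nm (liquid-phase simulation choice)
eps_rf: 78.3          # reaction-field dielectric beyond r_c
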