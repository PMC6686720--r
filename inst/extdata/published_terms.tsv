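molecule	torsion	t1	t2	t3	t4	n	K	chi0	ref_molecule	ref_torsion
beta0	phi1	C	NH1	CTB2	CTA2	1	0.27	180	-	-
beta0	phi1	C	NH1	CTB2	CTA2	2	0.16	0	-	-
beta0	phi1	C	NH1	CTB2	CTA2	3	0.29	180	-	-
beta0	phi3	H	NH1	CTB2	CTA2	1	0.27	0	beta0	phi1
beta0	phi3	H	NH1	CTB2	CTA2	2	0.16	0	beta0	phi1
beta0	phi3	H	NH1	CTB2	CTA2	3	0.29	0	beta0	phi1
beta0	theta1	NH1	CTB2	CTA2	C	3	0.94	0	-	-
beta0	theta1	NH1	CTB2	CTA2	C	6	0.07	0	-	-
beta0	psi1	CTB2	CTA2	C	NH1	1	0.68	0	-	-
beta0	psi1	CTB2	CTA2	C	NH1	2	0.21	180	-	-
beta0	psi1	CTB2	CTA2	C	NH1	3	0.13	180	-	-
beta0	psi2	CTB2	CTA2	C	O	1	0.68	180	beta0	psi1
beta0	psi2	CTB2	CTA2	C	O	2	0.21	180	beta0	psi1
beta0	psi2	CTB2	CTA2	C	O	3	0.13	0	beta0	psi1
beta2	phi1	C	NH1	CTB2	CTB1	1	0.11	0	-	-
beta2	phi1	C	NH1	CTB2	CTB1	2	0.41	0	-	-
beta2	phi1	C	NH1	CTB2	CTB1	3	0.42	180	-	-
beta2	phi1	C	NH1	CTB2	CTB1	6	0.20	0	-	-
beta2	phi3	H	NH1	CTB2	CTB1	1	0.11	180	beta2	phi1
beta2	phi3	H	NH1	CTB2	CTB1	2	0.41	0	beta2	phi1
beta2	phi3	H	NH1	CTB2	CTB1	3	0.42	0	beta2	phi1
beta2	phi3	H	NH1	CTB2	CTB1	6	0.20	0	beta2	phi1
beta2	theta1	NH1	CTB2	CTB1	C	3	0.43	0	-	-
beta2	theta1	NH1	CTB2	CTB1	C	6	0.21	0	-	-
beta2	theta2	NH1	CTB2	CTB1	CT3	3	0.43	0	beta2	theta1
beta2	theta2	NH1	CTB2	CTB1	CT3	6	0.21	0	beta2	theta1
beta2	psi1	CTB2	CTB1	C	NH1	1	0.46	0	-	-
beta2	psi1	CTB2	CTB1	C	NH1	2	0.26	0	-	-
beta2	psi1	CTB2	CTB1	C	NH1	3	0.03	180	-	-
beta2	psi1	CTB2	CTB1	C	NH1	6	0.01	0	-	-
beta2	psi2	CTB2	CTB1	C	O	1	0.46	180	beta2	psi1
beta2	psi2	CTB2	CTB1	C	O	2	0.26	0	beta2	psi1
beta2	psi2	CTB2	CTB1	C	O	3	0.03	0	beta2	psi1
beta2	psi2	CTB2	CTB1	C	O	6	0.01	0	beta2	psi1
beta2	psi3	CT3	CTB1	C	NH1	1	0.51	0	-	-
beta2	psi3	CT3	CTB1	C	NH1	2	0.35	0	-	-
beta2	psi3	CT3	CTB1	C	NH1	3	0.03	180	beta2	psi1
beta2	psi3	CT3	CTB1	C	NH1	6	0.01	0	beta2	psi1
beta2	psi4	CT3	CTB1	C	O	1	0.51	180	beta2	psi3
beta2	psi4	CT3	CTB1	C	O	2	0.35	0	beta2	psi3
beta2	psi4	CT3	CTB1	C	O	3	0.03	0	beta2	psi1
beta2	psi4	CT3	CTB1	C	O	6	0.01	0	beta2	psi1
beta3	phi1	C	NH1	CTA1	CTA2	1	0.18	180	-	-
beta3	phi1	C	NH1	CTA1	CTA2	2	0.12	0	-	-
beta3	phi1	C	NH1	CTA1	CTA2	3	0.03	0	-	-
beta3	phi1	C	NH1	CTA1	CTA2	6	0.04	180	-	-
beta3	phi2	C	NH1	CTA1	CT3	1	0.14	180	-	-
beta3	phi2	C	NH1	CTA1	CT3	2	0.04	0	-	-
beta3	phi2	C	NH1	CTA1	CT3	3	0.03	0	beta3	phi1
beta3	phi2	C	NH1	CTA1	CT3	6	0.04	180	beta3	phi1
beta3	phi4	H	NH1	CTA1	CTA2	1	0.18	0	beta3	phi1
beta3	phi4	H	NH1	CTA1	CTA2	2	0.12	0	beta3	phi1
beta3	phi4	H	NH1	CTA1	CTA2	3	0.03	180	beta3	phi1
beta3	phi4	H	NH1	CTA1	CTA2	6	0.04	180	beta3	phi1
beta3	phi5	H	NH1	CTA1	CT3	1	0.14	0	beta3	phi2
beta3	phi5	H	NH1	CTA1	CT3	2	0.04	0	beta3	phi2
beta3	phi5	H	NH1	CTA1	CT3	3	0.03	180	beta3	phi1
beta3	phi5	H	NH1	CTA1	CT3	6	0.04	180	beta3	phi1
beta3	theta1	NH1	CTA1	CTA2	C	3	0.54	0	-	-
beta3	theta1	NH1	CTA1	CTA2	C	6	0.03	180	-	-
beta3	theta3	CT3	CTA1	CTA2	C	3	0.54	0	beta3	theta1
beta3	theta3	CT3	CTA1	CTA2	C	6	0.03	180	beta3	theta1
beta3	theta5	HB1	CTA1	CTA2	C	3	0.54	0	beta3	theta1
beta3	theta5	HB1	CTA1	CTA2	C	6	0.03	180	beta3	theta1
beta3	psi1	CTA1	CTA2	C	NH1	1	0.23	0	-	-
beta3	psi1	CTA1	CTA2	C	NH1	2	0.36	180	-	-
beta3	psi1	CTA1	CTA2	C	NH1	3	0.30	180	-	-
beta3	psi1	CTA1	CTA2	C	NH1	6	0.02	0	-	-
beta3	psi2	CTA1	CTA2	C	O	1	0.23	180	beta3	psi1
beta3	psi2	CTA1	CTA2	C	O	2	0.36	180	beta3	psi1
beta3	psi2	CTA1	CTA2	C	O	3	0.30	0	beta3	psi1
beta3	psi2	CTA1	CTA2	C	O	6	0.02	0	beta3	psi1
beta23	phi1	C	NH1	CTA1	CTB1	1	0.35	180	-	-
beta23	phi1	C	NH1	CTA1	CTB1	2	0.13	0	-	-
beta23	phi1	C	NH1	CTA1	CTB1	3	0.03	0	beta3	phi1
beta23	phi1	C	NH1	CTA1	CTB1	6	0.04	180	beta3	phi1
beta23	phi4	H	NH1	CTA1	CTB1	1	0.35	0	beta23	phi1
beta23	phi4	H	NH1	CTA1	CTB1	2	0.13	0	beta23	phi1
beta23	phi4	H	NH1	CTA1	CTB1	3	0.03	180	beta3	phi1
beta23	phi4	H	NH1	CTA1	CTB1	6	0.04	180	beta3	phi1
beta23	theta1	NH1	CTA1	CTB1	C	3	0.24	0	-	-
beta23	theta1	NH1	CTA1	CTB1	C	6	0.02	0	-	-
beta23	theta2	NH1	CTA1	CTB1	CT3	3	0.24	0	beta23	theta1
beta23	theta2	NH1	CTA1	CTB1	CT3	6	0.02	0	beta23	theta1
beta23	theta4	CT3	CTA1	CTB1	C	3	0.24	0	beta23	theta1
beta23	theta4	CT3	CTA1	CTB1	C	6	0.02	0	beta23	theta1
beta23	theta5	CT3	CTA1	CTB1	CT3	3	0.24	0	beta23	theta1
beta23	theta5	CT3	CTA1	CTB1	CT3	6	0.02	0	beta23	theta1
beta23	psi1	CTA1	CTB1	C	NH1	1	0.64	0	-	-
beta23	psi1	CTA1	CTB1	C	NH1	2	0.06	180	-	-
beta23	psi1	CTA1	CTB1	C	NH1	3	0.03	180	beta2	psi1
beta23	psi1	CTA1	CTB1	C	NH1	6	0.01	0	beta2	psi1
beta23	psi2	CTA1	CTB1	C	O	1	0.64	180	beta23	psi1
beta23	psi2	CTA1	CTB1	C	O	2	0.06	180	beta23	psi1
beta23	psi2	CTA1	CTB1	C	O	3	0.03	0	beta2	psi1
beta23	psi2	CTA1	CTB1	C	O	6	0.01	0	beta2	psi1
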