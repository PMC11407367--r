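category,category_code,indicator,code
Prevent,p,Antimicrobial resistance (AMR),p11
Prevent,p,Zoonotic disease,p12
Prevent,p,Biosecurity,p13
Prevent,p,Biosafety,p14
Prevent,p,Dual-use research and culture of responsible science,p15
Prevent,p,Immunization,p16
Detect,d,Laboratory systems strength and quality,d21
Detect,d,Laboratory supply chains,d22
Detect,d,Real-time surveillance and reporting,d23
Detect,d,Surveillance data accessibility and transparency,d24
Detect,d,Case-based investigation,d25
Detect,d,Epidemiology workforce,d26
Respond,r,Emergency preparedness and response planning,r31
Respond,r,Exercising response plans,r32
Respond,r,Emergency response operation,r33
Respond,r,Linking public health and security authorities,r34
Respond,r,Risk communication,r35
Respond,r,Access to communications infrastructure,r36
Respond,r,Trade and travel restrictions,r37
Health,h,"Health capacity in clinics, hospitals, and community care centers",h41
Health,h,Supply chain for health system and healthcare workers,h42
Health,h,Medical countermeasures and personnel deployment,h43
Health,h,Healthcare access,h44
Health,h,Communications with healthcare workers during a public health emergency,h45
Health,h,Infection control practices,h46
Health,h,Capacity to test and approve new medical countermeasures,h47
Norms,n,IHR reporting compliance and disaster risk reduction,n51
Norms,n,Cross-border agreements on public health and animal health emergency response,n52
Norms,n,International commitments,n53
Norms,n,JEE and PVS,n54
Norms,n,Financing,n55
Norms,n,Commitment to sharing of genetic & biological data & specimens,n56
Risk,r,Political and security risk,r61
Risk,r,Socioeconomic resilience,r62
Risk,r,Infrastructure adequacy,r63
Risk,r,Environmental risks,r64
Risk,r,Public health vulnerabilities,r65
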