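# MedDRA preferred terms (v23.0) defining the drug-induced liver injury
# event set. One term per line; matching is case-insensitive with
# whitespace collapsed. Lines starting with '#' are ignored.
Liver injury
Liver damage
Liver necrosis
Hepatic damage
Hepatotoxicity
Hepatopathy
Hepatic disease
Hepatitis
Nonalcoholic fatty liver disease
Liver fatty infiltration
Steatohepatitis
Hepatic steatosis
Jaundice
Icterus
Cholestasis
Bile duct damage
Biliary cholangitis
Hepatobiliary disease
Hepatic encephalopathy
Hepatic failure
Hepatic vascular injury
Hepatic cirrhosis
Portal hypertension
DILI
Hepatic necrosis
Hepatocellular injury
Hepatomegaly
Hepatic enzyme abnormal
Hepatic enzyme increased
Transaminases increased
Transaminases abnormal
Blood bilirubin abnormal
Blood bilirubin increased
Aspartate aminotransferase abnormal
Aspartate aminotransferase increased
Hepatic injury
Hepatic function abnormal
Hepatocellular damage
Cirrhosis
Hyperbilirubinaemia
Liver transplant
Alanine aminotransferase abnormal
Alanine aminotransferase increased
Ammonia increased
Bilirubin conjugated increased
Bilirubin urine
Blood bilirubin unconjugated increased
Coma hepatic
Hyperammonaemia
Liver function test abnormal
Mixed hepatocellular-cholestatic injury
Urine bilirubin increased
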