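code,name,l2,l3
kyphosis,Convex sagittal spinal curvature,Spine,Shape
lordosis,Concave sagittal spinal curvature,Spine,Shape
scoliosis,Lateral (coronal) spinal curvature,Spine,Shape
spine-curvature,Unspecified abnormal spinal curvature,Spine,Shape
vertebral-morphology,Abnormal vertebral morphology,Spine,Morphology
spine-morphology,Abnormal overall spine morphology,Spine,Morphology
vertebral-fusion,Fused vertebrae,Spine,Fusion
cervical-displacement,Displaced cervical vertebrae,Spine,Cervical
cervical-count,Abnormal cervical vertebra count,Spine,Cervical
thoracic-displacement,Displaced thoracic vertebrae,Spine,Thoracic
thoracic-count,Abnormal thoracic vertebra count,Spine,Thoracic
lumbar-displacement,Displaced lumbar vertebrae,Spine,Lumbar
lumbar-count,Abnormal lumbar vertebra count,Spine,Lumbar
caudal-truncation,Truncated caudal (tail) spine,Spine,Caudal
caudal-kink,Kinked caudal vertebrae,Spine,Caudal
caudal-count,Abnormal caudal vertebra count,Spine,Caudal
sacral-anomaly,Sacral region anomaly,Spine,Other
vertebral-other,Other vertebral anomaly,Spine,Other
rib-fusion,Fused or merged ribs,Ribcage,Fusion
rib-count,Abnormal number of ribs,Ribcage,Other
rib-shape,Abnormal rib shape,Ribcage,Shape
rib-morphology,Abnormal rib morphology,Ribcage,Morphology
sternum-anomaly,Sternum anomaly,Ribcage,Other
costal-joint-anomaly,Costal joint anomaly,Ribcage,Joints
clavicle-anomaly,Clavicle anomaly,Whole-body,Other
scapula-anomaly,Scapula anomaly,Whole-body,Other
pelvis-anomaly,Pelvis anomaly,Whole-body,Other
joint-dislocation,Dislocated joint,Whole-body,Joints
joint-fusion,Fused joint,Whole-body,Fusion
body-morphology,Abnormal whole-body skeletal morphology,Whole-body,Morphology
body-shape,Abnormal whole-body skeletal shape,Whole-body,Shape
skeletal-mineralization,Abnormal skeletal mineralization,Whole-body,Other
whole-body-other,Other whole-body anomaly,Whole-body,Other
syndactylism,Fused digits (syndactylism),Limbs,Digits
polydactyly,Supernumerary digits,Limbs,Digits
brachydactyly,Shortened digits,Limbs,Digits
digit-integrity,Abnormal digit integrity,Limbs,Digits
femur-anomaly,Femur anomaly,Limbs,Other
fibula-anomaly,Fibula anomaly,Limbs,Other
humerus-anomaly,Humerus anomaly,Limbs,Other
tibia-anomaly,Tibia anomaly,Limbs,Other
ulna-anomaly,Ulna anomaly,Limbs,Other
radius-anomaly,Radius anomaly,Limbs,Other
limb-joint-anomaly,Limb joint anomaly,Limbs,Joints
limb-morphology,Abnormal limb morphology,Limbs,Morphology
mandible-anomaly,Mandible anomaly,Skull,Other
maxilla-anomaly,Maxilla / pre-maxilla anomaly,Skull,Other
premaxilla-anomaly,Pre-maxilla anomaly,Skull,Other
teeth-anomaly,Teeth anomaly,Skull,Other
zygomatic-anomaly,Zygomatic bone anomaly,Skull,Other
skull-shape,Abnormal skull shape,Skull,Shape
skull-morphology,Abnormal skull morphology,Skull,Morphology
cranial-fusion,Premature cranial suture fusion,Skull,Fusion
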